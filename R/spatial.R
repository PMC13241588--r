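#' Watercourse (flow-line) distance between network points
#'
#' Sum of edge lengths along the unique tree path between two snapped network
#' nodes.
#'
#' @param net a \linkS4class{StreamNetwork}
#' @param a,b node ids (vectors allowed; the result is the
#'   \code{length(a) x length(b)} distance matrix, dropped to a scalar when
#'   both are single ids)
#' @return distances in km
#' @export
watercourseDistance <- function(net, a, b) {
  g <- .net_graph(net)
  ids <- igraph::V(g)$name
  if (!all(c(a, b) %in% ids)) stop("points must be snapped to network nodes")
  d <- igraph::distances(g, v = a, to = b, weights = igraph::E(g)$length)
  if (any(!is.finite(d))) stop("points lie in different network components")
  if (length(a) == 1L && length(b) == 1L) d[1, 1] else d
}

.net_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net@edges$from, to = net@edges$to,
               length = net@edges$length),
    directed = FALSE,
    vertices = net@nodes$node)
}

#' Pairwise distance matrix over network points
#'
#' @param net a \linkS4class{StreamNetwork}
#' @param nodes node ids
#' @param metric "watercourse" (along the network) or "euclidean" (straight
#'   line in the planar km coordinates)
#' @return symmetric matrix with zero diagonal, dimnames = \code{nodes}
#' @export
distanceMatrix <- function(net, nodes, metric = c("watercourse", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "watercourse") {
    d <- watercourseDistance(net, nodes, nodes)
    if (!is.matrix(d)) d <- matrix(d, 1, 1)
  } else {
    idx <- match(nodes, net@nodes$node)
    if (anyNA(idx)) stop("unknown node id")
    xy <- as.matrix(net@nodes[idx, c("x", "y")])
    d <- as.matrix(stats::dist(xy))
  }
  dimnames(d) <- list(nodes, nodes)
  attr(d, "metric") <- metric
  d
}

#' Empirical semivariogram over distance bins
#'
#' gamma(h) = (1 / (2 N_h)) * sum over pairs in bin h of (v_i - v_j)^2, with
#' equal-width bins spanning (0, max distance] (or equal-count bins on the
#' pair distances). Bins supported by fewer than \code{min_pairs} pairs are
#' retained but flagged \code{low_support}. A locally-weighted (loess)
#' smoothing of gamma over bin midpoints is attached when at least four
#' supported bins exist.
#'
#' @param values named numeric vector of point values (e.g. unit random
#'   intercepts); names index the distance matrix
#' @param D symmetric distance matrix from \code{\link{distanceMatrix}}
#' @param n_bins number of distance bins (default 20)
#' @param min_pairs minimum pairs for full support (default 21)
#' @param binning "equal_width" or "equal_count"
#' @param span loess span for the smoothing curve (default 0.7)
#' @return data.frame: bin edges, mean pair distance, semivariance
#'   \code{gamma}, \code{n_pairs}, \code{low_support}, \code{gamma_smooth};
#'   attributes record metric, span and binning
#' @export
empiricalSemivariogram <- function(values, D, n_bins = 20L, min_pairs = 21L,
                                   binning = c("equal_width", "equal_count"),
                                   span = 0.7) {
  binning <- match.arg(binning)
  metric <- attr(D, "metric")
  nm <- names(values)
  if (!is.null(nm)) D <- D[nm, nm, drop = FALSE]
  n <- length(values)
  stopifnot(n >= 2, nrow(D) == n)
  ut <- upper.tri(D)
  h <- D[ut]
  sq <- (outer(values, values, "-")^2)[ut]
  if (binning == "equal_width") {
    edges <- seq(0, max(h), length.out = n_bins + 1L)
  } else {
    edges <- unique(quantile(h, probs = seq(0, 1, length.out = n_bins + 1L)))
  }
  bin <- cut(h, breaks = edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1L
  out <- data.frame(bin = seq_len(nb), lower = edges[-length(edges)],
                    upper = edges[-1])
  out$n_pairs <- as.integer(tabulate(bin, nbins = nb))
  out$mean_distance <- vapply(seq_len(nb), function(b)
    if (out$n_pairs[b]) mean(h[bin == b]) else NA_real_, numeric(1))
  out$gamma <- vapply(seq_len(nb), function(b)
    if (out$n_pairs[b]) sum(sq[bin == b]) / (2 * out$n_pairs[b]) else NA_real_,
    numeric(1))
  out$low_support <- out$n_pairs < min_pairs
  out$gamma_smooth <- NA_real_
  ok <- !is.na(out$gamma)
  if (sum(ok) >= 4) {
    sm <- tryCatch(
      suppressWarnings(loess(gamma ~ mean_distance, data = out[ok, ],
                             span = span, degree = 1,
                             weights = out$n_pairs[ok])),
      error = function(e) NULL)
    if (!is.null(sm)) out$gamma_smooth[ok] <- predict(sm)
  }
  attr(out, "metric") <- metric
  attr(out, "span") <- span
  attr(out, "binning") <- binning
  out
}

#' Inflection proxy for a semivariogram
#'
#' Flags fine-scale patchiness: the first interior bin where the first
#' difference of the smoothed semivariance falls below half the initial
#' slope. Returns the bin's mean distance, or NA when the curve keeps rising
#' steadily (pure gradient).
#'
#' @param sv data.frame from \code{\link{empiricalSemivariogram}}
#' @return list: \code{inflection_km} (NA if none), \code{detected}
#' @export
semivariogramInflection <- function(sv) {
  ok <- !is.na(sv$gamma_smooth) & !sv$low_support
  g <- sv$gamma_smooth[ok]; dmid <- sv$mean_distance[ok]
  if (length(g) < 4) return(list(inflection_km = NA_real_, detected = FALSE))
  d1 <- diff(g) / diff(dmid)
  init <- mean(d1[1:2])
  if (!is.finite(init) || init <= 0)
    return(list(inflection_km = NA_real_, detected = FALSE))
  hit <- which(d1 < init / 2)
  hit <- hit[hit > 1]
  if (!length(hit)) return(list(inflection_km = NA_real_, detected = FALSE))
  list(inflection_km = dmid[hit[1] + 1L], detected = TRUE)
}

#' Linear trend of unit intercepts against the latitude proxy
#'
#' Ordinary least squares of random intercepts on latitude (planar northing
#' km for synthetic data, degrees for real data), with a 95\% confidence
#' interval on the slope.
#'
#' @param intercepts named numeric vector of per-unit values
#' @param latitude numeric vector aligned with \code{intercepts}
#' @return list: \code{slope}, \code{intercept}, \code{ci} (2-vector),
#'   \code{fit} (the \code{lm} object)
#' @export
latitudeTrend <- function(intercepts, latitude) {
  stopifnot(length(intercepts) == length(latitude), length(intercepts) >= 3)
  if (sd(latitude) == 0) stop("latitude proxy has zero variance")
  fit <- lm(intercepts ~ latitude)
  ci <- confint(fit, "latitude", level = 0.95)
  list(slope = unname(coef(fit)["latitude"]),
       intercept = unname(coef(fit)[1]),
       ci = as.numeric(ci), fit = fit)
}

#' Distribution of unit intercepts by geographic region
#'
#' @param intercepts named numeric vector of per-unit values
#' @param region_ids character vector aligned with \code{intercepts}
#' @param latitude optional latitude proxy used to order regions north to
#'   south (by region mean)
#' @return data.frame: region, n, mean, sd, min, max; plus the among/within
#'   variance F-ratio in \code{attr(, "f_ratio")}
#' @export
regionSummary <- function(intercepts, region_ids, latitude = NULL) {
  stopifnot(length(intercepts) == length(region_ids))
  sp <- split(intercepts, region_ids)
  out <- data.frame(region = names(sp),
                    n = lengths(sp),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, sd, numeric(1)),
                    min = vapply(sp, min, numeric(1)),
                    max = vapply(sp, max, numeric(1)),
                    row.names = NULL)
  if (!is.null(latitude)) {
    cen <- vapply(split(latitude, region_ids), mean, numeric(1))
    out <- out[order(-cen[out$region]), ]
    rownames(out) <- NULL
  }
  attr(out, "f_ratio") <- if (length(sp) > 1) {
    fit <- stats::anova(lm(intercepts ~ factor(region_ids)))
    fit[["F value"]][1]
  } else NA_real_
  out
}
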