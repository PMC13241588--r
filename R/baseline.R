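#' Weir-Cockerham FST (theta) among groups
#'
#' Per-locus variance components a (among groups), b (among individuals
#' within groups) and c (within individuals) of Weir & Cockerham (1984),
#' combined across loci as a ratio of sums. Monomorphic loci contribute zero
#' components rather than NaN. Returns the global estimate over all groups
#' and the symmetric pairwise matrix.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param grouping vector of group labels (one per individual), or the name
#'   of a metadata column (default "collection_id")
#' @return list: \code{global} (scalar theta), \code{pairwise} (symmetric
#'   matrix, zero diagonal), \code{groups}
#' @export
weirCockerhamFst <- function(G, grouping = "collection_id") {
  if (length(grouping) == 1L) grouping <- sampleInfo(G)[[grouping]]
  stopifnot(length(grouping) == nIndividuals(G))
  d <- refDosage(G)$dosage
  groups <- sort(unique(grouping))
  if (length(groups) < 2) stop("need at least two groups")
  st <- .group_stats(d, grouping, groups)
  glob <- .wc_theta(st$n, st$p, st$h)
  K <- length(groups)
  pw <- matrix(0, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    pw[i, j] <- pw[j, i] <-
      .wc_theta(st$n[c(i, j), , drop = FALSE], st$p[c(i, j), , drop = FALSE],
                st$h[c(i, j), , drop = FALSE])
  }
  list(global = glob, pairwise = pw, groups = groups)
}

# per-group, per-locus called counts, ref-allele frequency, heterozygote freq
.group_stats <- function(d, grouping, groups) {
  K <- length(groups); L <- ncol(d)
  n <- p <- h <- matrix(0, K, L)
  for (k in seq_len(K)) {
    dk <- d[grouping == groups[k], , drop = FALSE]
    called <- colSums(!is.na(dk))
    n[k, ] <- called
    p[k, ] <- ifelse(called > 0, colSums(dk, na.rm = TRUE) / (2 * called), NA)
    h[k, ] <- ifelse(called > 0, colMeans(dk == 1, na.rm = TRUE), NA)
  }
  list(n = n, p = p, h = h)
}

# ratio-of-sums Weir-Cockerham theta from group summary matrices (groups x loci)
.wc_theta <- function(n, p, h) {
  r <- nrow(n)
  use <- colSums(n >= 1) == r & colSums(n) > r   # every group called, nbar > 1
  n <- n[, use, drop = FALSE]; p <- p[, use, drop = FALSE]
  h <- h[, use, drop = FALSE]
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- is.finite(a) & is.finite(b) & is.finite(cc) & nc > 0
  sum(a[ok]) / sum((a + b + cc)[ok])
}

#' Build reporting units from a baseline and a collection-to-unit map
#'
#' @param G a baseline \linkS4class{GenotypeMatrix}
#' @param groups named list mapping \code{unit_id} to a character vector of
#'   collection ids (default: one unit per collection)
#' @param stream_ids optional named vector: stream id per collection (falls
#'   back to the \code{stream_id} metadata column, then to the collection id)
#' @param point_nodes optional named vector: network point node per unit
#' @return a \linkS4class{BaselineUnits}
#' @export
baselineUnits <- function(G, groups = NULL, stream_ids = NULL,
                          point_nodes = NULL) {
  info <- sampleInfo(G)
  if (is.null(groups)) {
    colls <- sort(unique(info$collection_id))
    groups <- as.list(colls); names(groups) <- colls
  }
  if (is.null(stream_ids)) {
    if (!is.null(info$stream_id)) {
      stream_ids <- tapply(info$stream_id, info$collection_id,
                           function(x) x[1])
    } else {
      colls <- unique(info$collection_id)
      stream_ids <- setNames(colls, colls)
    }
  }
  rd <- refDosage(G)
  U <- length(groups); L <- nLoci(G)
  ref <- tot <- matrix(0, U, L,
                       dimnames = list(names(groups), locusNames(G)))
  n_ind <- integer(U)
  for (u in seq_len(U)) {
    idx <- info$collection_id %in% groups[[u]]
    du <- rd$dosage[idx, , drop = FALSE]
    ref[u, ] <- colSums(du, na.rm = TRUE)
    tot[u, ] <- 2 * colSums(!is.na(du))
    n_ind[u] <- sum(idx)
  }
  streams <- vapply(groups, function(cs)
    paste(sort(unique(stream_ids[cs])), collapse = "+"), character(1))
  units <- data.frame(unit_id = names(groups),
                      collection_ids = vapply(groups, paste, character(1),
                                              collapse = ","),
                      n_individuals = n_ind,
                      stream_id = streams,
                      point_node = if (is.null(point_nodes)) NA_character_
                                   else unname(point_nodes[names(groups)]),
                      stringsAsFactors = FALSE)
  new("BaselineUnits", units = units, ref_counts = ref, tot_counts = tot,
      alleles = rd$alleles)
}

#' Leave-one-out self-assignment of baseline individuals
#'
#' Each baseline individual's two alleles per locus are subtracted from its
#' own group's counts before its genotype likelihood for that group is
#' computed; posteriors are likelihood times a uniform prior over groups.
#' The confusion matrix aggregates posterior probability by true group (rows
#' sum to 1); an argmax-rate variant counts hard assignments.
#'
#' @param G a baseline \linkS4class{GenotypeMatrix}
#' @param groups named list mapping group id to collection ids (default one
#'   group per collection)
#' @return list: \code{posteriors} (individuals x groups),
#'   \code{confusion}, \code{argmax_confusion}, \code{self_rates} (diagonal
#'   of \code{confusion}), \code{weighted_mean} (self-assignment rate
#'   weighted by group size), \code{group_of} (true group per individual)
#' @export
selfAssignment <- function(G, groups = NULL) {
  units <- baselineUnits(G, groups)
  info <- sampleInfo(G)
  gmap <- .collection_to_unit(units)
  true_g <- unname(gmap[info$collection_id])
  if (anyNA(true_g)) stop("individual in a collection outside the grouping")
  rd <- refDosage(G, units@alleles)
  ll <- .loglik_matrix(rd$dosage, unitPosteriorFreqs(units))
  # leave-one-out correction for the individual's own group
  uid <- match(true_g, unitIds(units))
  X <- units@ref_counts; TT <- units@tot_counts
  for (i in seq_len(nrow(ll))) {
    u <- uid[i]
    di <- rd$dosage[i, ]
    called <- !is.na(di)
    x <- X[u, called] - di[called]
    tt <- TT[u, called] - 2
    if (any(tt <= 0))
      rg_warn("leave-one-out empties group '%s' at %d loci; prior-only frequencies used",
              unitIds(units)[u], sum(tt <= 0))
    p <- (x + 0.5) / (tt + 1)
    dc <- di[called]
    ll[i, u] <- sum(dc * log(p) + (2 - dc) * log(1 - p) + (dc == 1) * log(2))
  }
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  K <- ncol(post)
  conf <- rowsum(post, true_g) / as.vector(table(true_g)[sort(unique(true_g))])
  amax <- unitIds(units)[max.col(post)]
  aconf <- as.matrix(table(factor(true_g, levels = unitIds(units)),
                           factor(amax, levels = unitIds(units))))
  aconf <- aconf / rowSums(aconf)
  self <- diag(conf[unitIds(units), unitIds(units), drop = FALSE])
  wts <- table(true_g)[unitIds(units)]
  list(posteriors = post, confusion = conf[unitIds(units), , drop = FALSE],
       argmax_confusion = aconf, self_rates = self,
       weighted_mean = sum(self * wts) / sum(wts), group_of = true_g)
}

.collection_to_unit <- function(units) {
  tab <- units@units
  cs <- strsplit(tab$collection_ids, ",", fixed = TRUE)
  setNames(rep(tab$unit_id, lengths(cs)), unlist(cs))
}

#' Iteratively aggregate confusable collections into reporting units
#'
#' Merges the pair of current groups with the lowest pairwise theta among
#' pairs satisfying all of: (i) one group's self-assignment rate is below
#' \code{self_rate_threshold} and its largest off-diagonal posterior mass
#' flows to the other; (ii) pairwise Weir-Cockerham theta is strictly below
#' \code{fst_threshold}; (iii) both groups come from the same tributary
#' stream. Self-assignment and theta are recomputed after every merge; the
#' process stops when no pair qualifies (or a merge would exceed
#' \code{max_collections} collections).
#'
#' @param G a baseline \linkS4class{GenotypeMatrix}
#' @param stream_ids named vector: stream id per collection (defaults as in
#'   \code{\link{baselineUnits}})
#' @param self_rate_threshold flag collections below this self-assignment
#'   rate (default 0.7)
#' @param fst_threshold strict upper bound on pairwise theta (default 0.01)
#' @param max_collections cap on collections per merged unit (default 3)
#' @return list: \code{groups} (named list unit -> collections),
#'   \code{history} (data.frame of merges), \code{self_assignment} (final),
#'   \code{fst} (final pairwise matrix)
#' @export
aggregateCollections <- function(G, stream_ids = NULL,
                                 self_rate_threshold = 0.7,
                                 fst_threshold = 0.01,
                                 max_collections = 3L) {
  info <- sampleInfo(G)
  colls <- sort(unique(info$collection_id))
  if (is.null(stream_ids)) {
    stream_ids <- if (!is.null(info$stream_id))
      tapply(info$stream_id, info$collection_id, function(x) x[1])
    else setNames(colls, colls)
  }
  groups <- as.list(colls); names(groups) <- colls
  history <- list()
  repeat {
    sa <- selfAssignment(G, groups)
    grouping <- sa$group_of
    fst <- weirCockerhamFst(G, grouping)
    ids <- names(groups)
    conf <- sa$confusion[ids, ids, drop = FALSE]
    self <- sa$self_rates[ids]
    stream_of <- vapply(groups, function(cs) {
      s <- unique(stream_ids[cs]); if (length(s) == 1) s else NA_character_
    }, character(1))
    cand <- NULL
    for (i in seq_along(ids)) {
      if (self[i] >= self_rate_threshold) next
      off <- conf[i, ]; off[i] <- -Inf
      j <- which.max(off)
      if (j == i) next
      th <- fst$pairwise[ids[i], ids[j]]
      if (!(th < fst_threshold)) next
      if (is.na(stream_of[i]) || is.na(stream_of[j]) ||
          stream_of[i] != stream_of[j]) next
      if (length(groups[[i]]) + length(groups[[j]]) > max_collections) next
      cand <- rbind(cand, data.frame(i = i, j = j, theta = th))
    }
    if (is.null(cand)) break
    best <- cand[which.min(cand$theta), ]
    i <- best$i; j <- best$j
    merged <- sort(c(groups[[i]], groups[[j]]))
    history[[length(history) + 1L]] <-
      data.frame(merged_into = paste(merged, collapse = "+"),
                 from = ids[i], to = ids[j], theta = best$theta)
    groups[[min(i, j)]] <- merged
    names(groups)[min(i, j)] <- paste(merged, collapse = "+")
    groups[[max(i, j)]] <- NULL
  }
  sa <- selfAssignment(G, groups)
  fst <- weirCockerhamFst(G, sa$group_of)
  list(groups = groups,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame(),
       self_assignment = sa, fst = fst)
}

#' Exclude small unaggregated collections
#'
#' Single-collection groups with \code{n <= max_n} individuals are dropped
#' (aggregation was attempted first and not feasible for them); collections
#' of any size inside merged units are retained.
#'
#' @param groups named list mapping unit -> collection ids (from
#'   \code{\link{aggregateCollections}})
#' @param G the baseline \linkS4class{GenotypeMatrix}
#' @param max_n exclusion threshold (default 5: drop n <= 5)
#' @return list: \code{groups} (retained), \code{report} (data.frame of
#'   excluded collections with sizes)
#' @export
excludeSmallCollections <- function(groups, G, max_n = 5L) {
  sizes <- table(sampleInfo(G)$collection_id)
  excl <- list()
  keep <- groups
  for (u in names(groups)) {
    if (length(groups[[u]]) == 1L && sizes[groups[[u]]] <= max_n) {
      excl[[u]] <- data.frame(collection_id = groups[[u]],
                              n = as.integer(sizes[groups[[u]]]))
      keep[[u]] <- NULL
    }
  }
  list(groups = keep,
       report = if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
                else data.frame(collection_id = character(), n = integer()))
}
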