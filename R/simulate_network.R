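#' Simulation configuration for the synthetic riverscape
#'
#' Defaults emulate the study system this package targets: ~52 tributary
#' source populations genotyped at 266 SNP loci with a global FST near 0.04,
#' 30-40 individuals sampled per collection (with a fraction arising from
#' full-sib families), a 6-section main stem sampled over 3 years at ~500
#' mixture fish per year, and connectivity categories with counts
#' connected=39, culvert/diversion=3, low flow=7, waterfall=3.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_populations number of tributary source populations.
#' @param n_loci number of biallelic SNP loci.
#' @param theta_fst target among-population differentiation (Balding-Nichols
#'   theta).
#' @param n_per_collection length-2 integer range of individuals per baseline
#'   collection.
#' @param sib_family_rate fraction of baseline individuals generated as
#'   members of full-sib families.
#' @param n_sections number of main-stem sections.
#' @param n_years number of mixture sampling years.
#' @param mixture_size_per_year adult trout sampled per year across sections.
#' @param connectivity_counts named integer vector over the four categories;
#'   must sum to \code{n_populations}.
#' @param zib_coefficients forward-model coefficients from
#'   \code{\link{zibCoefficients}}.
#' @param main_stem_km total main-stem length.
#' @param point_offset_km length-2 range: how far up its tributary each
#'   population's sampling point sits.
#' @param missing_rate per-call missing-genotype probability.
#' @param split_populations number of populations sampled as two collections
#'   at different points on the same stream (the rest have one collection).
#' @param n_regions number of geographic regions used for patchy spatial
#'   effects.
#' @param year_mode "constant" holds true contributions fixed across years;
#'   "iid" redraws them each year.
#' @return a list of class \code{riverscape_config}
#' @export
simulationConfig <- function(seed = 1L,
                             n_populations = 52L,
                             n_loci = 266L,
                             theta_fst = 0.04,
                             n_per_collection = c(30L, 40L),
                             sib_family_rate = 0.15,
                             n_sections = 6L,
                             n_years = 3L,
                             mixture_size_per_year = 500L,
                             connectivity_counts = c(connected = 39L,
                                                     culvert_diversion = 3L,
                                                     low_flow = 7L,
                                                     waterfall = 3L),
                             zib_coefficients = zibCoefficients(),
                             main_stem_km = 90,
                             point_offset_km = c(1, 5),
                             missing_rate = 0.02,
                             split_populations = 0L,
                             n_regions = 8L,
                             year_mode = c("constant", "iid")) {
  stopifnot(theta_fst > 0, theta_fst < 1, n_populations >= 1, n_sections >= 1,
            sum(connectivity_counts) == n_populations)
  cfg <- list(seed = as.integer(seed), n_populations = as.integer(n_populations),
              n_loci = as.integer(n_loci), theta_fst = theta_fst,
              n_per_collection = as.integer(n_per_collection),
              sib_family_rate = sib_family_rate,
              n_sections = as.integer(n_sections), n_years = as.integer(n_years),
              mixture_size_per_year = as.integer(mixture_size_per_year),
              connectivity_counts = connectivity_counts,
              zib_coefficients = zib_coefficients,
              main_stem_km = main_stem_km, point_offset_km = point_offset_km,
              missing_rate = missing_rate,
              split_populations = as.integer(split_populations),
              n_regions = as.integer(n_regions),
              year_mode = match.arg(year_mode))
  class(cfg) <- "riverscape_config"
  cfg
}

#' Generate a dendritic stream network
#'
#' Builds a north-to-south main stem of \code{n_sections} equal sections with
#' midpoint nodes, and one tributary per source population whose mouth is
#' attached at a uniformly drawn main-stem position. Each population's
#' sampling point sits a configurable distance up its tributary. The result
#' is a tree, so watercourse distances are unique-path sums.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @return a \linkS4class{StreamNetwork}
#' @export
generateNetwork <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$main_stem_km; S <- cfg$n_sections; R <- cfg$n_populations
  seclen <- L / S
  # positions measured as km upstream from the outlet; upstream = north
  mouth_pos <- runif(R, 0, L)
  mid_pos <- L - (seq_len(S) - 0.5) * seclen          # section A is northmost
  bnd_pos <- seq(0, L, by = seclen)
  pos <- sort(unique(c(mouth_pos, mid_pos, bnd_pos)), decreasing = TRUE)
  ms_ids <- paste0("ms", seq_along(pos))
  nodes <- data.frame(node = ms_ids, x = 0, y = pos,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ms_ids[-length(ms_ids)], to = ms_ids[-1],
                      length = -diff(pos), stringsAsFactors = FALSE)
  edges <- edges[edges$length > 0, ]
  pop_id <- sprintf("P%02d", seq_len(R))
  mouth_node <- ms_ids[match(mouth_pos, pos)]
  offs <- runif(R, cfg$point_offset_km[1], cfg$point_offset_km[2])
  side <- sample(c(-1, 1), R, replace = TRUE)
  pnodes <- data.frame(node = paste0("pt_", pop_id), x = side * offs,
                       y = mouth_pos, stringsAsFactors = FALSE)
  pedges <- data.frame(from = mouth_node, to = pnodes$node, length = offs,
                       stringsAsFactors = FALSE)
  sections <- data.frame(section = LETTERS[seq_len(S)],
                         midpoint_node = ms_ids[match(mid_pos, pos)],
                         stringsAsFactors = FALSE)
  populations <- data.frame(pop_id = pop_id, mouth_node = mouth_node,
                            point_node = pnodes$node, stringsAsFactors = FALSE)
  new("StreamNetwork", nodes = rbind(nodes, pnodes),
      edges = rbind(edges, pedges), sections = sections,
      populations = populations, main_stem = ms_ids)
}

#' Generate tributary covariates with known spatial structure
#'
#' Catchment area is lognormal; the groundwater index follows a north-south
#' gradient plus patchy regional effects (so semivariogram diagnostics have
#' known signal); connectivity categories are assigned to match the
#' configured counts exactly. The same latitude proxy and regional patches
#' also drive the true mean-contribution intercepts used by
#' \code{\link{simulateTrueContributions}}.
#'
#' @param net a \linkS4class{StreamNetwork} from \code{\link{generateNetwork}}
#' @param cfg a \code{\link{simulationConfig}}
#' @return data.frame with one row per source population: \code{pop_id},
#'   \code{point_node}, \code{northing_km} (latitude proxy),
#'   \code{region_id}, \code{area_km2}, \code{groundwater},
#'   \code{connectivity}, and the true contribution intercept
#'   \code{alpha_unit_true}.
#' @export
generateCovariates <- function(net, cfg) {
  set.seed(cfg$seed + 1L)
  pops <- net@populations
  R <- nrow(pops)
  if (sum(cfg$connectivity_counts) != R)
    stop("connectivity_counts must sum to n_populations")
  northing <- net@nodes$y[match(pops$point_node, net@nodes$node)]
  zn <- as.numeric(scale(northing))
  # contiguous regions along the main stem, like sub-watersheds
  nr <- min(cfg$n_regions, R)
  region <- paste0("R", as.integer(cut(rank(-northing, ties.method = "first"),
                                       breaks = nr, labels = FALSE)))
  region_g <- rnorm(nr, 0, 0.7)
  region_mu <- rnorm(nr, 0, cfg$zib_coefficients$sd_region)
  ridx <- as.integer(sub("R", "", region))
  groundwater <- plogis(1.2 * zn + region_g[ridx] + rnorm(R, 0, 0.5))
  area <- stats::rlnorm(R, meanlog = log(40), sdlog = 0.9)
  conn <- rep(names(cfg$connectivity_counts), cfg$connectivity_counts)
  conn <- sample(conn, R)
  # latitudinal gradient (south-high) + regional patches in the true intercepts
  alpha_unit <- cfg$zib_coefficients$lat_slope * zn + region_mu[ridx] +
    rnorm(R, 0, cfg$zib_coefficients$sd_unit)
  data.frame(pop_id = pops$pop_id, point_node = pops$point_node,
             northing_km = northing, region_id = region,
             area_km2 = area, groundwater = groundwater,
             connectivity = factor(conn, levels = names(cfg$connectivity_counts)),
             alpha_unit_true = alpha_unit, stringsAsFactors = FALSE)
}
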