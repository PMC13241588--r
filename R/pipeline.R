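#' Pipeline configuration
#'
#' Bundles the input source (a simulation configuration or file paths), the
#' filtering thresholds used throughout the chain, sampler settings and the
#' seed. Exactly one of \code{simulation} and \code{paths} must be given.
#'
#' @param simulation a \code{\link{simulationConfig}}, or NULL
#' @param paths list with \code{genotypes} (one table holding baseline and
#'   mixture rows) plus optional \code{covariates} and network tables, or
#'   NULL
#' @param call_rate minimum individual call rate (default 0.85)
#' @param sib_threshold full-sib relatedness cutoff (default 0.4)
#' @param self_rate_threshold aggregation flag (default 0.7)
#' @param fst_threshold aggregation bound (default 0.01)
#' @param small_collection_n exclusion size (default 5)
#' @param assignment_threshold dispersal-summary posterior cutoff (default
#'   0.7)
#' @param gsi_sweeps,gsi_burn Gibbs settings for mixture fits
#' @param bootstrap_B bootstrap replicates per stratum
#' @param zib_chains,zib_warmup,zib_iter contribution-model settings
#' @param dirichlet_chains,dirichlet_warmup,dirichlet_iter composition-model
#'   settings
#' @param run_dirichlet run the five-hypothesis composition comparison
#'   (exact-refit LOO; the slowest stage)
#' @param seed master seed
#' @return list of class \code{pipeline_config}
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           paths = NULL,
                           call_rate = 0.85, sib_threshold = 0.4,
                           self_rate_threshold = 0.7, fst_threshold = 0.01,
                           small_collection_n = 5L,
                           assignment_threshold = 0.7,
                           gsi_sweeps = 2000L, gsi_burn = 500L,
                           bootstrap_B = 100L,
                           zib_chains = 4L, zib_warmup = 2000L,
                           zib_iter = 2000L,
                           dirichlet_chains = 3L, dirichlet_warmup = 2000L,
                           dirichlet_iter = 2000L,
                           run_dirichlet = TRUE,
                           seed = 1L) {
  if (is.null(simulation) == is.null(paths))
    stop("exactly one of 'simulation' and 'paths' must be supplied")
  stopifnot(call_rate > 0, call_rate <= 1, sib_threshold > 0,
            self_rate_threshold > 0, self_rate_threshold <= 1,
            fst_threshold > 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# exact-zero convention: a unit's contribution in a stratum is 0 when no
# individual assigns to it by maximum posterior AND its corrected proportion
# is below 1/(2 * stratum size); surviving entries are renormalized
.apply_zero_convention <- function(pi_corr, indiv_post) {
  n <- nrow(indiv_post)
  has_argmax <- tabulate(max.col(indiv_post), nbins = ncol(indiv_post)) > 0
  zero <- !has_argmax & pi_corr < 1 / (2 * n)
  p <- pi_corr
  p[zero] <- 0
  if (sum(p) > 0) p <- p / sum(p)
  p
}

#' Per-stratum contribution table from mixture fits
#'
#' Applies the exact-zero convention (no maximum-posterior assignee and a
#' corrected proportion below half an individual's worth) and renormalizes,
#' yielding the compositions consumed by the regression modules.
#'
#' @param fits list of \linkS4class{MixtureFit} with corrected proportions
#' @return data.frame: section, year, unit_id, p
#' @export
contributionsFromFits <- function(fits) {
  rows <- lapply(fits, function(f) {
    p <- .apply_zero_convention(
      if (length(f@pi_corrected)) f@pi_corrected else f@pi_mean,
      f@indiv_posteriors)
    data.frame(section = f@stratum$section, year = f@stratum$year,
               unit_id = f@unit_ids, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full inference chain
#'
#' Sequences quality control, the sibling filter, baseline aggregation,
#' per-stratum mixture estimation with bootstrap correction and z-scores,
#' the composition model comparison, the covariate (zero-inflated beta)
#' model, and spatial diagnostics on its unit intercepts. With a simulation
#' config the synthetic riverscape supplies all inputs and the truth is
#' carried along for validation.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return list of stage results plus a \code{report} summarizing counts,
#'   thresholds and seeds
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulation)) {
    sim <- simulateRiverscape(config$simulation)
    baseline_raw <- sim$baseline; mixture_raw <- sim$mixture
    net <- sim$network; truth <- sim$truth
  } else {
    G <- readGenotypeTable(config$paths$genotypes)
    info <- sampleInfo(G)
    baseline_raw <- G[info$role == "baseline", ]
    mixture_raw <- G[info$role == "mixture", ]
    net <- config$paths$network
    if (is.character(net)) net <- readStreamNetwork(net)
    truth <- if (!is.null(config$paths$covariates))
      read.table(config$paths$covariates, header = TRUE, sep = ",",
                 stringsAsFactors = FALSE) else NULL
    sim <- NULL
  }

  # --- qc ---------------------------------------------------------------
  base_qc <- filterByCallRate(baseline_raw, config$call_rate)
  mix_qc <- filterByCallRate(mixture_raw, config$call_rate)
  panel <- locusPanel(locusNames(base_qc))
  all_qc <- GenotypeMatrix(
    rbind(base_qc@allele1, mix_qc@allele1),
    rbind(base_qc@allele2, mix_qc@allele2),
    .rbind_info(sampleInfo(base_qc), sampleInfo(mix_qc)))
  dl <- dropLoci(all_qc, panel)
  keep_loci <- locusNames(dl$genotypes)
  base_qc <- base_qc[, keep_loci]; mix_qc <- mix_qc[, keep_loci]

  # --- sibling filter ---------------------------------------------------
  sib <- siblingFilter(base_qc, config$sib_threshold)
  base_f <- sib$genotypes

  # --- baseline aggregation --------------------------------------------
  agg <- aggregateCollections(base_f,
                              self_rate_threshold = config$self_rate_threshold,
                              fst_threshold = config$fst_threshold)
  excl <- excludeSmallCollections(agg$groups, base_f,
                                  config$small_collection_n)
  keep_ids <- sampleInfo(base_f)$collection_id %in% unlist(excl$groups)
  base_final <- base_f[keep_ids, ]
  point_nodes <- NULL
  if (!is.null(truth) && !is.null(truth$point_node)) {
    pop_of_unit <- vapply(excl$groups, function(cs)
      unique(sub("[ab]$", "", cs))[1], character(1))
    point_nodes <- setNames(
      truth$point_node[match(pop_of_unit, truth$pop_id)], names(excl$groups))
  }
  units <- baselineUnits(base_final, excl$groups, point_nodes = point_nodes)
  sa <- selfAssignment(base_final, excl$groups)

  # --- mixture analysis -------------------------------------------------
  strata <- splitStrata(mix_qc)
  empty <- vapply(strata, function(g) nIndividuals(g) == 0, logical(1))
  strata <- strata[!empty]
  fits <- list()
  for (k in seq_along(strata)) {
    f <- fitMixture(units, strata[[k]], sweeps = config$gsi_sweeps,
                    burn = config$gsi_burn, seed = config$seed + 10L + k)
    f <- bootstrapCorrect(f, units, B = config$bootstrap_B,
                          seed = config$seed + 500L + k)
    f@z_scores <- zScores(strata[[k]], f, units)
    fits[[names(strata)[k]]] <- f
  }
  contrib <- contributionsFromFits(fits)
  disp <- if (!is.null(net))
    dispersalSummary(fits, net, units, config$assignment_threshold) else NULL

  # --- composition model comparison ------------------------------------
  dirichlet <- NULL
  if (isTRUE(config$run_dirichlet)) {
    ymat <- .contrib_matrix(contrib)
    obs <- data.frame(section = sub("_.*", "", rownames(ymat)),
                      year = sub(".*_", "", rownames(ymat)))
    dfits <- lapply(1:5, function(h) {
      fitZoiDirichlet(ymat, buildDesign(obs, h),
                      chains = config$dirichlet_chains,
                      warmup = config$dirichlet_warmup,
                      iter = config$dirichlet_iter,
                      seed = config$seed + 900L + h)
    })
    dirichlet <- list(fits = dfits,
                      comparison = looCompare(dfits,
                                              seed = config$seed + 950L))
  }

  # --- covariate model --------------------------------------------------
  zib <- NULL; spatial <- NULL
  if (!is.null(truth) && !is.null(net)) {
    zdata <- .zib_table(contrib, units, truth, net)
    zib <- fitZib(zdata, chains = config$zib_chains,
                  warmup = config$zib_warmup, iter = config$zib_iter,
                  seed = config$seed + 700L)
    spatial <- .spatial_stage(zib, units, truth, net)
  }

  report <- list(
    n_baseline_raw = nIndividuals(baseline_raw),
    n_baseline_qc = nIndividuals(base_qc),
    n_baseline_final = nIndividuals(base_final),
    n_mixture_raw = nIndividuals(mixture_raw),
    n_mixture_qc = nIndividuals(mix_qc),
    n_loci = length(keep_loci),
    n_units = nrow(unitTable(units)),
    merges = if (nrow(agg$history)) nrow(agg$history) else 0L,
    excluded_collections = excl$report,
    weighted_self_assignment = sa$weighted_mean,
    thresholds = config[c("call_rate", "sib_threshold",
                          "self_rate_threshold", "fst_threshold",
                          "small_collection_n", "assignment_threshold")],
    seed = config$seed,
    runtime_s = as.numeric(Sys.time() - t0, units = "secs"))

  list(simulation = sim, units = units, self_assignment = sa,
       aggregation = agg, mixture_fits = fits, contributions = contrib,
       dispersal = disp, dirichlet = dirichlet, zib = zib,
       spatial = spatial, report = report)
}

.rbind_info <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[, cols], b[, cols])
}

.contrib_matrix <- function(contrib) {
  key <- paste(contrib$section, contrib$year, sep = "_")
  units <- sort(unique(contrib$unit_id))
  strata <- sort(unique(key))
  y <- matrix(0, length(strata), length(units),
              dimnames = list(strata, units))
  y[cbind(match(key, strata), match(contrib$unit_id, units))] <- contrib$p
  y
}

# assemble the long ZIB observation table: per (unit, section, year), the
# estimated contribution plus that unit's covariates and its distance to the
# section midpoint
.zib_table <- function(contrib, units, truth, net) {
  ut <- unitTable(units)
  pop <- vapply(strsplit(ut$collection_ids, ","), function(cs)
    unique(sub("[ab]$", "", cs))[1], character(1))
  tr <- truth[match(pop, truth$pop_id), ]
  d <- contrib
  idx <- match(d$unit_id, ut$unit_id)
  d$pop_id <- pop[idx]
  mids <- net@sections$midpoint_node
  D <- watercourseDistance(net, tr$point_node, mids)
  rownames(D) <- ut$unit_id; colnames(D) <- net@sections$section
  d$distance_km <- D[cbind(match(d$unit_id, ut$unit_id),
                           match(d$section, net@sections$section))]
  d$area_km2 <- tr$area_km2[idx]
  d$groundwater <- tr$groundwater[idx]
  d$connectivity <- tr$connectivity[idx]
  d
}

.spatial_stage <- function(zib, units, truth, net) {
  ut <- unitTable(units)
  pop <- vapply(strsplit(ut$collection_ids, ","), function(cs)
    unique(sub("[ab]$", "", cs))[1], character(1))
  tr <- truth[match(pop, truth$pop_id), ]
  a_cols <- grep("^alpha_unit\\[", zib@pars)
  a_mean <- colMeans(zib@draws[, a_cols, drop = FALSE])
  # the model's unit labels are population ids (one population per unit)
  unit_of_col <- sub("^alpha_unit\\[(.*)\\]$", "\\1", zib@pars[a_cols])
  idx2 <- match(unit_of_col, pop)
  a_mean <- setNames(a_mean, tr$point_node[idx2])
  lat <- tr$northing_km[idx2]
  region <- tr$region_id[idx2]
  Dw <- distanceMatrix(net, names(a_mean), "watercourse")
  De <- distanceMatrix(net, names(a_mean), "euclidean")
  list(intercepts = data.frame(unit_id = unit_of_col, alpha = unname(a_mean),
                               northing_km = lat, region_id = region),
       semivariogram_watercourse = empiricalSemivariogram(a_mean, Dw),
       semivariogram_euclidean = empiricalSemivariogram(a_mean, De),
       latitude_trend = latitudeTrend(unname(a_mean), lat),
       region_summary = regionSummary(unname(a_mean), region, lat))
}

#' Composition summary by section and groundwater class
#'
#' Per-section mean contribution per unit (averaged over years, with the
#' range across years), and aggregate shares by groundwater index bands —
#' the numbers behind a per-section composition figure.
#'
#' @param fits list of \linkS4class{MixtureFit} (or a contributions
#'   data.frame from \code{\link{contributionsFromFits}})
#' @param units a \linkS4class{BaselineUnits}
#' @param groundwater named vector: groundwater index per unit (names =
#'   unit ids)
#' @param bands groundwater band edges (default 0, 1/3, 2/3, 1)
#' @return list: \code{by_unit} (section, unit, mean/min/max contribution),
#'   \code{by_band} (section x band share matrix)
#' @export
reportComposition <- function(fits, units, groundwater,
                              bands = c(0, 1 / 3, 2 / 3, 1)) {
  contrib <- if (is.data.frame(fits)) fits else contributionsFromFits(fits)
  sp <- split(contrib, list(contrib$section, contrib$unit_id), drop = TRUE)
  by_unit <- do.call(rbind, lapply(sp, function(d)
    data.frame(section = d$section[1], unit_id = d$unit_id[1],
               mean_p = mean(d$p), min_p = min(d$p), max_p = max(d$p))))
  by_unit <- by_unit[order(by_unit$section, by_unit$unit_id), ]
  rownames(by_unit) <- NULL
  gw <- groundwater[by_unit$unit_id]
  band <- cut(gw, breaks = bands, include.lowest = TRUE)
  secs <- sort(unique(by_unit$section))
  share <- t(vapply(secs, function(s) {
    i <- by_unit$section == s
    tapply(by_unit$mean_p[i], band[i], sum, default = 0)
  }, numeric(nlevels(band))))
  share <- share / rowSums(share)
  rownames(share) <- secs
  list(by_unit = by_unit, by_band = share)
}
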