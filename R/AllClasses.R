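#' @import methods
#' @importFrom stats rbeta rbinom rgamma rnorm runif rmultinom rhyper quantile
#'   sd var median plogis qlogis setNames aggregate lm confint coef glm
#'   binomial loess predict model.matrix cor dbeta rpois pbinom qbinom
#'   complete.cases na.omit optim dnorm
#' @importFrom utils read.table write.table head
NULL

setOldClass("igraph")

#' Diploid SNP genotypes with sample metadata
#'
#' Individuals by loci container for two-allele SNP calls. Allele codes are
#' stored verbatim in two character matrices (one per gene copy); a missing
#' genotype is \code{NA} in both. Baseline individuals carry a collection id,
#' mixture individuals a main-stem section and year.
#'
#' @slot allele1,allele2 character matrices (individuals x loci) of allele
#'   codes; \code{NA} marks a missing call (always in both slots at once).
#' @slot info data.frame with one row per individual: \code{individual_id},
#'   \code{collection_id}, \code{role} ("baseline" or "mixture"),
#'   \code{section}, \code{year}, plus any extra columns (e.g. simulation
#'   truth labels).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(allele1 = "matrix", allele2 = "matrix", info = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  a1 <- object@allele1; a2 <- object@allele2; info <- object@info
  if (!identical(dim(a1), dim(a2))) msg <- c(msg, "allele matrices differ in shape")
  if (nrow(info) != nrow(a1)) msg <- c(msg, "info rows != individuals")
  if (!all(c("individual_id", "collection_id", "role", "section", "year") %in%
             names(info)))
    msg <- c(msg, "info lacks required metadata columns")
  if (anyDuplicated(info$individual_id))
    msg <- c(msg, "duplicate individual_id")
  if (any(is.na(a1) != is.na(a2)))
    msg <- c(msg, "missingness must be all-or-nothing within a locus call")
  if (!is.null(colnames(a1)) && anyDuplicated(colnames(a1)))
    msg <- c(msg, "locus names not unique")
  if (length(msg)) msg else TRUE
})

#' Dendritic stream network with main-stem sections and tributary points
#'
#' A tree-shaped network in planar km coordinates. The main stem is an ordered
#' node path split into sections, each with a midpoint node; every tributary
#' source population has a mouth node on the main stem and a sampling-point
#' node some distance up its tributary.
#'
#' @slot nodes data.frame: \code{node}, \code{x}, \code{y} (km).
#' @slot edges data.frame: \code{from}, \code{to}, \code{length} (km,
#'   positive), directed toward the outlet.
#' @slot sections data.frame: \code{section}, \code{midpoint_node}.
#' @slot populations data.frame: \code{pop_id}, \code{mouth_node},
#'   \code{point_node}.
#' @slot main_stem character vector of main-stem node ids, upstream first.
#' @exportClass StreamNetwork
setClass("StreamNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 sections = "data.frame", populations = "data.frame",
                 main_stem = "character"))

setValidity("StreamNetwork", function(object) {
  msg <- character()
  n <- nrow(object@nodes); e <- nrow(object@edges)
  if (e != n - 1L) msg <- c(msg, "not a tree: |edges| != |nodes| - 1")
  if (any(object@edges$length <= 0)) msg <- c(msg, "edge lengths must be > 0")
  ids <- object@nodes$node
  if (!all(c(object@edges$from, object@edges$to) %in% ids))
    msg <- c(msg, "edge endpoints missing from node table")
  if (!all(object@sections$midpoint_node %in% object@main_stem))
    msg <- c(msg, "section midpoints must lie on the main stem")
  if (length(msg)) msg else TRUE
})

#' Reporting units (aggregated baseline collections) with allele counts
#'
#' One row per reporting unit; per-locus reference-allele counts and total
#' called-allele counts. Units are the assignable stocks for mixture analysis.
#'
#' @slot units data.frame: \code{unit_id}, \code{collection_ids}
#'   (comma-separated), \code{n_individuals}, \code{stream_id},
#'   \code{point_node} (network point, may be NA).
#' @slot ref_counts,tot_counts numeric matrices (units x loci): count of the
#'   reference allele and total non-missing allele count (2 x called
#'   individuals).
#' @slot alleles data.frame: \code{locus}, \code{ref}, \code{alt} allele codes.
#' @exportClass BaselineUnits
setClass("BaselineUnits",
  representation(units = "data.frame", ref_counts = "matrix",
                 tot_counts = "matrix", alleles = "data.frame"))

setValidity("BaselineUnits", function(object) {
  msg <- character()
  if (!identical(dim(object@ref_counts), dim(object@tot_counts)))
    msg <- c(msg, "count matrices differ in shape")
  if (any(object@ref_counts < 0) || any(object@tot_counts < 0))
    msg <- c(msg, "negative allele counts")
  if (any(object@ref_counts > object@tot_counts))
    msg <- c(msg, "reference count exceeds total count")
  if (nrow(object@units) != nrow(object@ref_counts))
    msg <- c(msg, "unit table rows != count matrix rows")
  if (anyDuplicated(object@units$unit_id)) msg <- c(msg, "duplicate unit_id")
  if (length(msg)) msg else TRUE
})

#' Posterior mixture fit for one section-year stratum
#'
#' @slot stratum list with \code{section} and \code{year}.
#' @slot unit_ids character vector of reporting-unit ids (column order of all
#'   matrices).
#' @slot pi_mean posterior mean mixing proportions (simplex).
#' @slot pi_draws matrix of retained posterior draws (draws x units).
#' @slot indiv_posteriors matrix (individuals x units) of posterior mean
#'   responsibilities; rows sum to 1.
#' @slot pi_corrected bootstrap bias-corrected mixing proportions (simplex),
#'   length 0 until \code{bootstrapCorrect} is run.
#' @slot z_scores data.frame from \code{zScores}, may be empty.
#' @slot meta list: sweeps, burn-in, seed, prior.
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(stratum = "list", unit_ids = "character", pi_mean = "numeric",
                 pi_draws = "matrix", indiv_posteriors = "matrix",
                 pi_corrected = "numeric", z_scores = "data.frame",
                 meta = "list"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (abs(sum(object@pi_mean) - 1) > 1e-8)
    msg <- c(msg, "pi_mean not on the simplex")
  if (nrow(object@indiv_posteriors) > 0) {
    rs <- rowSums(object@indiv_posteriors)
    if (any(abs(rs - 1) > 1e-8))
      msg <- c(msg, "individual posterior rows must sum to 1")
  }
  if (length(object@pi_corrected) &&
      (any(object@pi_corrected < 0) ||
       abs(sum(object@pi_corrected) - 1) > 1e-8))
    msg <- c(msg, "corrected proportions must be a nonnegative simplex vector")
  if (length(msg)) msg else TRUE
})

#' Posterior fit of the hierarchical zero-inflated beta contribution model
#'
#' @slot draws matrix of posterior draws (draws x parameters), all chains
#'   pooled after warmup.
#' @slot chain integer vector mapping draws to chains.
#' @slot pars character vector of parameter names (columns of \code{draws}).
#' @slot data data.frame of model observations (unit, section, year, p and
#'   standardized covariates).
#' @slot scaling list recording the mean/sd used to standardize each
#'   continuous covariate.
#' @slot diagnostics data.frame: parameter, split-Rhat, effective sample size.
#' @slot pointwise_loglik matrix (draws x observations).
#' @slot meta list: chains, warmup, iterations, seed, priors.
#' @exportClass ZibFit
setClass("ZibFit",
  representation(draws = "matrix", chain = "integer", pars = "character",
                 data = "data.frame", scaling = "list",
                 diagnostics = "data.frame", pointwise_loglik = "matrix",
                 meta = "list"))

setValidity("ZibFit", function(object) {
  if (!all(is.finite(object@draws))) return("non-finite posterior draws")
  if (ncol(object@draws) != length(object@pars))
    return("pars do not label draw columns")
  TRUE
})

#' Posterior fit of the zero-and-one inflated Dirichlet composition model
#'
#' @slot draws matrix of posterior draws (draws x parameters).
#' @slot chain integer vector mapping draws to chains.
#' @slot pars parameter names.
#' @slot y observed composition matrix (observations x components).
#' @slot design model matrix used for the component means.
#' @slot hypothesis_id integer design hypothesis (1..5).
#' @slot pointwise_loglik matrix (draws x observations).
#' @slot diagnostics data.frame: parameter, split-Rhat, effective sample size.
#' @slot meta list: chains, warmup, iterations, seed.
#' @exportClass ZoiDirichletFit
setClass("ZoiDirichletFit",
  representation(draws = "matrix", chain = "integer", pars = "character",
                 y = "matrix", design = "matrix", hypothesis_id = "integer",
                 pointwise_loglik = "matrix", diagnostics = "data.frame",
                 meta = "list"))

setValidity("ZoiDirichletFit", function(object) {
  if (!all(is.finite(object@pointwise_loglik)))
    return("pointwise log-likelihood must be finite")
  TRUE
})
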