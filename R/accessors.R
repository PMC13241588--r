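#' @rdname GenotypeMatrix-class
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLoci", "GenotypeMatrix", function(x) ncol(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("locusNames", "GenotypeMatrix", function(x) colnames(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleInfo", "GenotypeMatrix", function(x) x@info)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("callRate", "GenotypeMatrix", function(x) {
  r <- rowMeans(!is.na(x@allele1))
  names(r) <- x@info$individual_id
  r
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nIndividuals(object), "individuals x",
      nLoci(object), "loci\n")
  tab <- table(object@info$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(object@allele1))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' Subset a GenotypeMatrix by individuals and/or loci
#'
#' @param x a \code{GenotypeMatrix}
#' @param i individual index (logical, integer or individual ids)
#' @param j locus index (logical, integer or locus names)
#' @param ... unused
#' @param drop ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@info$individual_id)
  new("GenotypeMatrix",
      allele1 = x@allele1[i, j, drop = FALSE],
      allele2 = x@allele2[i, j, drop = FALSE],
      info = x@info[i, , drop = FALSE])
})

#' @rdname BaselineUnits-class
#' @export
setMethod("unitIds", "BaselineUnits", function(x) x@units$unit_id)

#' @rdname BaselineUnits-class
#' @export
setMethod("unitTable", "BaselineUnits", function(x) x@units)

setMethod("show", "BaselineUnits", function(object) {
  cat("BaselineUnits:", nrow(object@units), "reporting units,",
      ncol(object@ref_counts), "loci\n")
  cat("  individuals per unit:",
      paste(range(object@units$n_individuals), collapse = "-"), "\n")
})

setMethod("show", "StreamNetwork", function(object) {
  cat("StreamNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (tree),",
      nrow(object@sections), "main-stem sections,",
      nrow(object@populations), "tributary populations\n")
})

#' @rdname MixtureFit-class
#' @param corrected return bootstrap-corrected proportions instead of the
#'   posterior mean
#' @export
setMethod("mixingProportions", "MixtureFit", function(x, corrected = FALSE) {
  p <- if (corrected) {
    if (!length(x@pi_corrected))
      stop("no bootstrap-corrected proportions; run bootstrapCorrect() first")
    x@pi_corrected
  } else x@pi_mean
  setNames(p, x@unit_ids)
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: section %s, year %s — %d individuals, %d units\n",
              object@stratum$section, object@stratum$year,
              nrow(object@indiv_posteriors), length(object@unit_ids)))
  top <- sort(mixingProportions(object), decreasing = TRUE)[1:min(3, length(object@unit_ids))]
  cat("  top units:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "ZibFit", function(x, ...) x@draws)

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "ZoiDirichletFit", function(x, ...) x@draws)

#' @rdname convergenceDiagnostics
#' @export
setMethod("convergenceDiagnostics", "ZibFit", function(x) x@diagnostics)

#' @rdname convergenceDiagnostics
#' @export
setMethod("convergenceDiagnostics", "ZoiDirichletFit", function(x) x@diagnostics)

#' @rdname pointwiseLoglik
#' @export
setMethod("pointwiseLoglik", "ZibFit", function(x) x@pointwise_loglik)

#' @rdname pointwiseLoglik
#' @export
setMethod("pointwiseLoglik", "ZoiDirichletFit", function(x) x@pointwise_loglik)

setMethod("show", "ZibFit", function(object) {
  cat("ZibFit:", nrow(object@draws), "posterior draws,",
      length(object@pars), "parameters,", nrow(object@data), "observations\n")
  bad <- sum(object@diagnostics$rhat >= 1.01, na.rm = TRUE)
  cat("  parameters with split-Rhat >= 1.01:", bad, "\n")
})

setMethod("show", "ZoiDirichletFit", function(object) {
  cat("ZoiDirichletFit: hypothesis", object@hypothesis_id, "-",
      nrow(object@draws), "draws,", nrow(object@y), "observations,",
      ncol(object@y), "components\n")
})
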