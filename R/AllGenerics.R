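#' @rdname GenotypeMatrix-class
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("callRate", function(x) standardGeneric("callRate"))

#' @rdname BaselineUnits-class
#' @param x a \code{BaselineUnits}
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname BaselineUnits-class
#' @export
setGeneric("unitTable", function(x) standardGeneric("unitTable"))

#' @rdname MixtureFit-class
#' @param x a \code{MixtureFit}
#' @export
setGeneric("mixingProportions",
           function(x, corrected = FALSE) standardGeneric("mixingProportions"))

#' Posterior draws of a Bayesian fit
#' @param x a fit object
#' @param ... unused
#' @export
setGeneric("posteriorDraws", function(x, ...) standardGeneric("posteriorDraws"))

#' Convergence diagnostics (split-Rhat, effective sample size)
#' @param x a fit object
#' @export
setGeneric("convergenceDiagnostics",
           function(x) standardGeneric("convergenceDiagnostics"))

#' Pointwise log-likelihood matrix (draws x observations)
#' @param x a fit object
#' @export
setGeneric("pointwiseLoglik", function(x) standardGeneric("pointwiseLoglik"))
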