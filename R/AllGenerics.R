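#' Individual identifiers of a genomic object
#' @param x a GenotypeMatrix or GRM.
#' @return character vector of identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@ids)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GRM", function(x) x@ids)

#' Allele count matrix of a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return integer matrix of reference-allele counts.
#' @export
setGeneric("genoCounts", function(x) standardGeneric("genoCounts"))

#' @rdname genoCounts
#' @export
setMethod("genoCounts", "GenotypeMatrix", function(x) x@counts)

#' Sample allele frequencies of a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return numeric vector of reference-allele frequencies.
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname alleleFreqs
#' @export
setMethod("alleleFreqs", "GenotypeMatrix", function(x) x@freqs)

#' SNP identifiers of a GenotypeMatrix
#' @param x a GenotypeMatrix.
#' @return character vector.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname snpIds
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@snpIds)

#' Relatedness values of a GRM
#' @param x a GRM.
#' @return symmetric numeric matrix.
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' @rdname grmValues
#' @export
setMethod("grmValues", "GRM", function(x) x@values)

#' Number of SNPs a GRM was computed from
#' @param x a GRM.
#' @return integer.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname nSnps
#' @export
setMethod("nSnps", "GRM", function(x) x@nSnps)

#' @export
setMethod("dim", "GRM", function(x) dim(x@values))

#' Subset a GRM by individual
#'
#' @param x a GRM.
#' @param i integer, logical or character (identifier) index.
#' @param j ignored; subsetting is symmetric in both margins.
#' @param ... ignored.
#' @param drop ignored.
#' @return a GRM restricted to the selected individuals.
#' @export
setMethod("[", "GRM", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("GRM", values = x@values[i, i, drop = FALSE], ids = x@ids[i],
      nSnps = x@nSnps)
})

#' Free-parameter names of a model spec
#' @param x an RNModelSpec.
#' @return character vector of parameter names.
#' @export
setGeneric("paramNames", function(x) standardGeneric("paramNames"))

#' @rdname paramNames
#' @export
setMethod("paramNames", "RNModelSpec", function(x) x@params$name)

#' Number of free parameters of a model spec
#' @param x an RNModelSpec.
#' @return integer.
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname nParams
#' @export
setMethod("nParams", "RNModelSpec", function(x) nrow(x@params))

#' Estimates of a REML fit
#' @param object an RNFit.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "RNFit", function(object, ...) object@estimates)

#' REML log-likelihood of a fit
#' @param object an RNFit.
#' @param ... ignored.
#' @export
setMethod("logLik", "RNFit", function(object, ...) object@logLik)

#' Standard errors of a REML fit
#' @param x an RNFit.
#' @return named numeric vector.
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname stdErrors
#' @export
setMethod("stdErrors", "RNFit", function(x) x@se)

#' Convergence flag of a REML fit
#' @param x an RNFit.
#' @return logical.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname isConverged
#' @export
setMethod("isConverged", "RNFit", function(x) x@converged)

#' Rejection proportion of a simulation experiment
#' @param x an ExperimentResult.
#' @return numeric rejection proportion at the experiment's alpha.
#' @export
setGeneric("rejectionRate", function(x) standardGeneric("rejectionRate"))

#' @rdname rejectionRate
#' @export
setMethod("rejectionRate", "ExperimentResult", function(x) x@rejectionRate)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@counts), "individuals x",
      ncol(object@counts), "SNPs\n")
  cat("  allele frequency range:",
      sprintf("[%.3f, %.3f]", min(object@freqs), max(object@freqs)), "\n")
})

setMethod("show", "GRM", function(object) {
  n <- nrow(object@values)
  cat("GRM:", n, "individuals,", object@nSnps, "SNPs\n")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.5f\n",
              mean(diag(object@values)),
              (sum(object@values) - sum(diag(object@values))) / (n * (n - 1))))
})

setMethod("show", "RNModelSpec", function(object) {
  cat("RNModelSpec:", object@variant,
      if (object@bivariate) "(bivariate)" else "(univariate)", "\n")
  cat("  free parameters (", nrow(object@params), "): ",
      paste(object@params$name, collapse = ", "), "\n", sep = "")
  if (object@covariate == "stratified")
    cat("  covariate stratified into", object@nGroups, "groups\n")
})

setMethod("show", "RNFit", function(object) {
  cat("RNFit:", object@spec@variant,
      if (object@converged) "(converged," else "(NOT converged,",
      object@nIter, "iterations)\n")
  tab <- data.frame(estimate = round(object@estimates, 4),
                    se = round(object@se, 4),
                    boundary = object@boundary)
  print(tab)
  cat("REML logLik:", format(object@logLik, digits = 8), "\n")
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT: statistic = %.4f on %d df, p = %.4g%s\n",
              object@statistic, object@df, object@pValue,
              if (object@valid) "" else "  [unconverged fit: flagged]"))
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@label, "\n")
  cat("  genetic covariance (alpha0, beta, alpha1):\n")
  print(object@sigmaG)
  cat("  residual covariance (tau0, eps, tau1):\n")
  print(object@sigmaR)
})

setMethod("show", "SimulatedData", function(object) {
  cat("SimulatedData:", length(object@y), "individuals,",
      object@design@label, "design, seed", object@seed, "\n")
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult:", nrow(object@replicates), "replicates",
      sprintf("(%d excluded as non-converged)\n", object@nExcluded))
  cat(sprintf("  rejection proportion at alpha = %.2f: %.3f;  lambda = %.3f\n",
              object@alpha, object@rejectionRate, object@lambda))
})
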