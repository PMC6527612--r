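#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: allele counts with per-SNP frequencies
#'
#' Container for an n x m matrix of reference-allele counts in \{0,1,2\},
#' together with individual identifiers, SNP identifiers and the sample
#' allele frequencies used for standardization.
#'
#' @slot counts integer matrix, individuals x SNPs, entries in \{0,1,2\}
#'   (NA allowed for missing genotypes read from file).
#' @slot ids character vector of individual identifiers ("FID_IID" keys).
#' @slot snpIds character vector of SNP identifiers.
#' @slot freqs numeric vector of reference-allele frequencies.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(counts = "matrix", ids = "character",
                 snpIds = "character", freqs = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  cnt <- object@counts
  if (nrow(cnt) < 2L || ncol(cnt) < 1L)
    return("need at least 2 individuals and 1 SNP")
  ok <- cnt %in% c(0L, 1L, 2L) | is.na(cnt)
  if (!all(ok)) return("genotype counts must be in {0, 1, 2} or NA")
  if (length(object@ids) != nrow(cnt)) return("ids do not match rows")
  if (length(object@snpIds) != ncol(cnt)) return("snpIds do not match columns")
  if (length(object@freqs) != ncol(cnt)) return("freqs do not match columns")
  TRUE
})

#' GRM: genomic relationship matrix
#'
#' Symmetric n x n SNP-based relatedness matrix A = W W' / m with
#' standardized genotypes W, as used by the GREML model family.
#'
#' @slot values symmetric numeric matrix of relatedness coefficients.
#' @slot ids character vector of individual identifiers.
#' @slot nSnps number of SNPs the matrix was computed from.
#' @exportClass GRM
setClass("GRM",
  representation(values = "matrix", ids = "character", nSnps = "integer"))

setValidity("GRM", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (length(object@ids) != nrow(v)) return("ids do not match dimension")
  if (max(abs(v - t(v))) > 1e-8 * (1 + max(abs(v))))
    return("values must be symmetric")
  if (any(diag(v) <= 0)) return("diagonal entries must be strictly positive")
  TRUE
})

#' RNModelSpec: declarative description of one model variant
#'
#' Describes which (co)variance parameters of the reaction norm family are
#' free, whether the model is univariate (trait only) or bivariate (trait
#' and covariate jointly), how the covariate enters (continuous polynomial
#' basis or stratified groups), and any bound constraints.
#'
#' @slot variant model name, e.g. "GREML", "RNM_GC", "MRNM_FULL".
#' @slot params data.frame with one row per free parameter: name, block
#'   ("yy", "yc", "cc"), base ("A", "I", "S", or "G<k>"), polynomial
#'   exponents l and r, and lower bound.
#' @slot bivariate logical; TRUE when y and c are modelled jointly.
#' @slot covariate "continuous" or "stratified".
#' @slot nGroups number of covariate strata for stratified variants.
#' @slot order polynomial order k of the reaction norm basis.
#' @slot standardize logical; centre/scale the covariate before basis
#'   construction when fitting.
#' @exportClass RNModelSpec
setClass("RNModelSpec",
  representation(variant = "character", params = "data.frame",
                 bivariate = "logical", covariate = "character",
                 nGroups = "integer", order = "integer",
                 standardize = "logical"))

setValidity("RNModelSpec", function(object) {
  p <- object@params
  need <- c("name", "block", "base", "l", "r", "lower")
  if (!all(need %in% names(p))) return("params must have columns name/block/base/l/r/lower")
  if (anyDuplicated(p$name)) return("duplicated parameter names")
  if (!all(p$block %in% c("yy", "yc", "cc"))) return("unknown block")
  if (!object@bivariate && any(p$block != "yy"))
    return("univariate spec cannot have yc/cc parameters")
  TRUE
})

#' RNFit: result of a REML fit
#'
#' @slot estimates named numeric vector of variance/covariance estimates.
#' @slot se named numeric vector of standard errors from the inverse
#'   average-information matrix (NA for parameters frozen at a bound).
#' @slot logLik REML log-likelihood at the optimum (constant convention:
#'   -0.5 * (log|V| + log|X'V^-1X| + y'Py); differences are
#'   convention-free).
#' @slot nIter number of iterations used.
#' @slot converged logical convergence flag.
#' @slot boundary logical vector; TRUE where a parameter ended on a bound.
#' @slot spec the RNModelSpec that was fitted.
#' @exportClass RNFit
setClass("RNFit",
  representation(estimates = "numeric", se = "numeric", logLik = "numeric",
                 nIter = "integer", converged = "logical",
                 boundary = "logical", spec = "RNModelSpec"))

#' LRTResult: likelihood-ratio test between nested REML fits
#'
#' @slot statistic 2 * (logL1 - logL0), clamped at zero.
#' @slot df difference in free-parameter count.
#' @slot pValue upper-tail chi-square probability.
#' @slot valid FALSE when either fit failed to converge.
#' @exportClass LRTResult
setClass("LRTResult",
  representation(statistic = "numeric", df = "integer", pValue = "numeric",
                 valid = "logical"))

#' SimulationDesign: generative design for phenotype/covariate simulation
#'
#' Holds the two 3 x 3 covariance matrices of the generative model: the
#' genetic covariance over (alpha0, beta, alpha1) and the residual
#' covariance over (tau0, eps, tau1).
#'
#' @slot sigmaG 3 x 3 symmetric PSD genetic covariance (alpha0, beta, alpha1).
#' @slot sigmaR 3 x 3 symmetric PSD residual covariance (tau0, eps, tau1).
#' @slot label human-readable design name.
#' @exportClass SimulationDesign
setClass("SimulationDesign",
  representation(sigmaG = "matrix", sigmaR = "matrix", label = "character"))

setValidity("SimulationDesign", function(object) {
  for (nm in c("sigmaG", "sigmaR")) {
    S <- slot(object, nm)
    if (!all(dim(S) == c(3L, 3L))) return(paste(nm, "must be 3 x 3"))
    if (max(abs(S - t(S))) > 1e-10) return(paste(nm, "must be symmetric"))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(sum(diag(S)), 1))
      return(paste(nm, "must be positive semidefinite"))
  }
  TRUE
})

#' SimulatedData: one simulated phenotype/covariate replicate
#'
#' @slot y phenotype vector.
#' @slot c covariate vector.
#' @slot components named list of the retained effect vectors
#'   (alpha0, alpha1c, tau0, tau1c, beta, eps); y and c are exact sums of
#'   their components.
#' @slot design the SimulationDesign used (the simulation truth).
#' @slot seed the seed the replicate was drawn with.
#' @exportClass SimulatedData
setClass("SimulatedData",
  representation(y = "numeric", c = "numeric", components = "list",
                 design = "SimulationDesign", seed = "integer"))

setValidity("SimulatedData", function(object) {
  cp <- object@components
  need <- c("alpha0", "alpha1c", "tau0", "tau1c", "beta", "eps")
  if (!all(need %in% names(cp))) return("missing component vectors")
  ysum <- cp$alpha0 + cp$alpha1c + cp$tau0 + cp$tau1c
  if (max(abs(object@y - ysum)) > 1e-12 * max(1, max(abs(object@y))))
    return("y is not the exact sum of its components")
  csum <- cp$beta + cp$eps
  if (max(abs(object@c - csum)) > 1e-12 * max(1, max(abs(object@c))))
    return("c is not the exact sum of its components")
  TRUE
})

#' ExperimentResult: summary of a replicated simulation experiment
#'
#' @slot replicates data.frame with one row per replicate (p-value, LRT
#'   statistic, selected estimates, convergence flag).
#' @slot rejectionRate proportion of converged replicates with p < alpha.
#' @slot lambda ratio of observed to expected median test statistic.
#' @slot alpha significance level used.
#' @slot nExcluded number of non-converged replicates excluded.
#' @exportClass ExperimentResult
setClass("ExperimentResult",
  representation(replicates = "data.frame", rejectionRate = "numeric",
                 lambda = "numeric", alpha = "numeric",
                 nExcluded = "integer"))
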