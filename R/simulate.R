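# Generative models for phenotype/covariate pairs under genotype-covariate
# and residual-covariate correlation and interaction.

.sqrt3 <- function(S, label) {
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(sum(diag(S)), 1))
    stop(label, " covariance is not positive semidefinite")
  t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
}

#' Named simulation designs
#'
#' Ships the generative designs used in the calibration, power and
#' inflation studies. Covariance order is (alpha0, beta, alpha1) on the
#' genetic side and (tau0, eps, tau1) on the residual side; tau0 plays
#' the role of the plain residual e when there is no residual-covariate
#' structure.
#'
#' \describe{
#'   \item{null}{independent unit-variance genetic/residual effects for
#'     y and c, no interaction and no cross-correlation.}
#'   \item{gc_power}{genetic interaction var(alpha1) = 0.25 with
#'     cov(alpha0, alpha1) = 0.05; everything else as in null.}
#'   \item{gc_corr_null}{genetic correlation cov(alpha0, beta) = 0.5 and
#'     residual correlation cov(tau0, eps) = 0.3, but no interaction:
#'     the design under which univariate interaction tests produce
#'     spurious signal.}
#'   \item{gc_grid}{gc_power with var(alpha1) set by \code{value}.}
#'   \item{rc_grid}{residual interaction var(tau1) = \code{value} with
#'     cov(tau0, tau1) = 0.05; genetic side additive.}
#' }
#'
#' @param name design name.
#' @param value grid value for the *_grid designs (var(alpha1) or
#'   var(tau1)).
#' @return a \linkS4class{SimulationDesign}.
#' @export
simPreset <- function(name = c("null", "gc_power", "gc_corr_null",
                               "gc_grid", "rc_grid"), value = 0) {
  name <- match.arg(name)
  Sg <- diag(c(1, 1, 0)); Sr <- diag(c(1, 1, 0))
  if (name == "gc_power") { Sg[1, 3] <- Sg[3, 1] <- 0.05; Sg[3, 3] <- 0.25 }
  if (name == "gc_corr_null") { Sg[1, 2] <- Sg[2, 1] <- 0.5
                                Sr[1, 2] <- Sr[2, 1] <- 0.3 }
  if (name == "gc_grid") { Sg[1, 3] <- Sg[3, 1] <- 0.05; Sg[3, 3] <- value }
  if (name == "rc_grid") { Sr[1, 3] <- Sr[3, 1] <- 0.05; Sr[3, 3] <- value }
  dimnames(Sg) <- list(c("alpha0", "beta", "alpha1"),
                       c("alpha0", "beta", "alpha1"))
  dimnames(Sr) <- list(c("tau0", "eps", "tau1"), c("tau0", "eps", "tau1"))
  new("SimulationDesign", sigmaG = Sg, sigmaR = Sr,
      label = if (name %in% c("gc_grid", "rc_grid"))
        sprintf("%s(%g)", name, value) else name)
}

#' Draw genetically correlated effect vectors
#'
#' Draws the three genetic coefficient vectors (alpha0, beta, alpha1)
#' jointly with covariance SigmaG (x) A - realized by applying a matrix
#' square root of A to iid standard-normal triples - and the residual
#' vectors (tau0, eps, tau1) with covariance SigmaR (x) I.
#'
#' @param A a \linkS4class{GRM}, a plain matrix, a precomputed factor
#'   L with L L' = A (pass \code{factor = TRUE} to skip refactoring when
#'   many replicates share one GRM), or a single integer n for the
#'   identity relationship of n unrelated individuals.
#' @param sigmaG 3 x 3 PSD genetic covariance over (alpha0, beta, alpha1).
#' @param sigmaR 3 x 3 PSD residual covariance over (tau0, eps, tau1).
#' @param seed integer seed.
#' @param factor set TRUE when A is already a square-root factor.
#' @return list of n-vectors alpha0, beta, alpha1, tau0, eps, tau1.
#' @export
drawCorrelatedEffects <- function(A, sigmaG, sigmaR, seed = 1L,
                                  factor = FALSE) {
  identityA <- is.numeric(A) && length(A) == 1L
  L <- if (identityA || factor) A else grmSquareRoot(A)
  n <- if (identityA) as.integer(A) else nrow(L)
  Mg <- .sqrt3(sigmaG, "genetic")
  Mr <- .sqrt3(sigmaR, "residual")
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * 3), n, 3)
  G <- (if (identityA) Z else L %*% Z) %*% Mg
  E <- matrix(stats::rnorm(n * 3), n, 3) %*% Mr
  list(alpha0 = G[, 1], beta = G[, 2], alpha1 = G[, 3],
       tau0 = E[, 1], eps = E[, 2], tau1 = E[, 3])
}

#' Simulate a phenotype/covariate pair under a full design
#'
#' Generates c = beta + eps and y = alpha0 + alpha1 * c + tau0 +
#' tau1 * c with the effect vectors drawn per
#' \code{\link{drawCorrelatedEffects}}. The covariate enters the product
#' terms raw (its variance is the sum of the design's beta and eps
#' variances, 2 under the shipped designs), so the proportion of
#' phenotypic variance due to interaction follows the design arithmetic
#' directly (e.g. var(alpha1) = 0.25 gives an interaction share of
#' 0.5 / 2.5 = 20 percent of var(y), i.e. var(alpha1)/var(y) = 10
#' percent).
#'
#' @param A GRM, matrix or square-root factor (see
#'   \code{\link{drawCorrelatedEffects}}).
#' @param design a \linkS4class{SimulationDesign}.
#' @param seed integer seed; replicate r of a batch conventionally uses
#'   \code{seed + r}.
#' @param factor TRUE when A is a precomputed factor.
#' @return a \linkS4class{SimulatedData}.
#' @export
simulateFull <- function(A, design, seed = 1L, factor = FALSE) {
  stopifnot(is(design, "SimulationDesign"))
  eff <- drawCorrelatedEffects(A, design@sigmaG, design@sigmaR,
                               seed = seed, factor = factor)
  cv <- eff$beta + eff$eps
  comp <- list(alpha0 = eff$alpha0, alpha1c = eff$alpha1 * cv,
               tau0 = eff$tau0, tau1c = eff$tau1 * cv,
               beta = eff$beta, eps = eff$eps)
  new("SimulatedData",
      y = comp$alpha0 + comp$alpha1c + comp$tau0 + comp$tau1c,
      c = cv, components = comp, design = design, seed = as.integer(seed))
}

#' Simulate under the genotype-covariate correlation/interaction model
#'
#' Convenience wrapper building the genetic covariance
#' [[1, covA0B, covA0A1], [covA0B, 1, 0], [covA0A1, 0, varAlpha1]] over
#' (alpha0, beta, alpha1) and the residual covariance
#' [[1, reCov, 0], [reCov, 1, 0], [0, 0, 0]] over (e, eps, tau1), then
#' drawing y = alpha0 + alpha1 * c + e with c = beta + eps.
#'
#' @param A GRM, matrix or factor.
#' @param varAlpha1 genetic interaction variance var(alpha1).
#' @param covA0A1 cov(alpha0, alpha1).
#' @param covA0B genotype-covariate genetic covariance cov(alpha0, beta).
#' @param reCov residual covariance cov(e, eps).
#' @param seed integer seed.
#' @param factor TRUE when A is a precomputed factor.
#' @return a \linkS4class{SimulatedData}.
#' @export
simulateGCCI <- function(A, varAlpha1 = 0.25, covA0A1 = 0.05, covA0B = 0,
                         reCov = 0, seed = 1L, factor = FALSE) {
  Sg <- matrix(c(1, covA0B, covA0A1,
                 covA0B, 1, 0,
                 covA0A1, 0, varAlpha1), 3, 3)
  Sr <- matrix(c(1, reCov, 0, reCov, 1, 0, 0, 0, 0), 3, 3)
  design <- new("SimulationDesign", sigmaG = Sg, sigmaR = Sr,
                label = sprintf("gcci(var_a1=%g)", varAlpha1))
  simulateFull(A, design, seed = seed, factor = factor)
}

#' Simulate under the residual-covariate correlation/interaction model
#'
#' Genetic side additive with cov(alpha0, beta) = covA0B; residual side
#' over (tau0, eps, tau1) with unit tau0/eps variances,
#' cov(tau0, tau1) = covT0T1, cov(tau0, eps) = covT0Eps and
#' var(tau1) = varTau1; y = alpha0 + tau0 + tau1 * c.
#'
#' @param A GRM, matrix or factor.
#' @param varTau1 residual interaction variance var(tau1).
#' @param covT0T1 cov(tau0, tau1).
#' @param covA0B cov(alpha0, beta).
#' @param covT0Eps residual-covariate covariance cov(tau0, eps).
#' @param seed integer seed.
#' @param factor TRUE when A is a precomputed factor.
#' @return a \linkS4class{SimulatedData}.
#' @export
simulateRCCI <- function(A, varTau1 = 0.25, covT0T1 = 0.05, covA0B = 0,
                         covT0Eps = 0, seed = 1L, factor = FALSE) {
  Sg <- matrix(c(1, covA0B, 0, covA0B, 1, 0, 0, 0, 0), 3, 3)
  Sr <- matrix(c(1, covT0Eps, covT0T1,
                 covT0Eps, 1, 0,
                 covT0T1, 0, varTau1), 3, 3)
  design <- new("SimulationDesign", sigmaG = Sg, sigmaR = Sr,
                label = sprintf("rcci(var_t1=%g)", varTau1))
  simulateFull(A, design, seed = seed, factor = factor)
}

#' Write a simulated replicate to phenotype/covariate/truth files
#'
#' Phenotype and covariate go to two-id text files (FID, IID, value);
#' the design matrices go to a plain-text truth sidecar (parameter name
#' = value lines).
#'
#' @param sim a \linkS4class{SimulatedData}.
#' @param ids individual identifiers ("FID_IID" keys).
#' @param prefix output path prefix; writes prefix.phen, prefix.covar,
#'   prefix.truth.
#' @return invisibly, the prefix.
#' @export
writeSimulatedData <- function(sim, ids, prefix) {
  stopifnot(length(ids) == length(sim@y))
  writePheno(ids, sim@y, paste0(prefix, ".phen"))
  writePheno(ids, sim@c, paste0(prefix, ".covar"))
  Sg <- sim@design@sigmaG; Sr <- sim@design@sigmaR
  gn <- c("alpha0", "beta", "alpha1"); rn <- c("tau0", "eps", "tau1")
  lines <- c(sprintf("design = %s", sim@design@label),
             sprintf("seed = %d", sim@seed))
  for (i in 1:3) for (j in i:3) {
    lines <- c(lines,
               sprintf("%s = %g",
                       if (i == j) sprintf("var(%s)", gn[i])
                       else sprintf("cov(%s,%s)", gn[i], gn[j]), Sg[i, j]),
               sprintf("%s = %g",
                       if (i == j) sprintf("var(%s)", rn[i])
                       else sprintf("cov(%s,%s)", rn[i], rn[j]), Sr[i, j]))
  }
  writeLines(lines, paste0(prefix, ".truth"))
  invisible(prefix)
}
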