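# REML engine for the reaction norm model family.
#
# All variants have covariance linear in the parameters,
# V(theta) = sum_p theta_p D_p, so first derivatives are the fixed D_p
# and the average-information matrix AI_pq = 0.5 u' D_p P D_q u with
# u = P y is available from O(n^2) structured products once P has been
# formed (one Cholesky + inversion per iteration).

.remlPrepare <- function(spec, data) {
  stopifnot(is(spec, "RNModelSpec"))
  y <- data$y
  n <- length(y)
  cRaw <- data$c
  groups <- data$groups
  cFit <- cRaw
  if (!is.null(cRaw) && spec@standardize)
    cFit <- if (is.matrix(cRaw)) apply(cRaw, 2, standardizeCovariate)
      else standardizeCovariate(cRaw)
  if (spec@covariate == "stratified" && is.null(groups)) {
    if (is.null(cFit)) stop("stratified spec needs a covariate")
    groups <- stratifyCovariate(cFit, spec@nGroups)
  }
  ctx <- .cvContext(spec, data$A, cFit, groups)
  if (spec@bivariate) {
    if (is.null(cFit)) stop("bivariate spec needs the covariate as trait 2")
    yObs <- c(y, cFit)
    X <- data$X
    if (is.null(X)) X <- rbind(cbind(rep(1, n), 0), cbind(0, rep(1, n)))
  } else {
    yObs <- y
    X <- data$X
    if (is.null(X)) X <- matrix(1, n, 1)
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  list(ctx = ctx, yObs = yObs, X = X, cFit = cFit, groups = groups)
}

# log-likelihood only (cheap candidate evaluation; no P)
.remlLLOnly <- function(ctx, theta, yObs, X) {
  V <- .cvV(ctx, theta)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdetV <- 2 * sum(log(diag(R)))
  solveV <- function(b) backsolve(R, forwardsolve(t(R), b))
  Viy <- solveV(yObs)
  ViX <- solveV(X)
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  XtViy <- crossprod(X, Viy)
  bhat <- backsolve(cX, forwardsolve(t(cX), XtViy))
  yPy <- sum(yObs * Viy) - sum(XtViy * bhat)
  -0.5 * (logdetV + 2 * sum(log(diag(cX))) + yPy)
}

# full evaluation with the projection matrix P
.remlCore <- function(ctx, theta, yObs, X) {
  V <- .cvV(ctx, theta)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdetV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  XtViXi <- chol2inv(cX)
  P <- Vi - ViX %*% tcrossprod(XtViXi, ViX)
  Py <- drop(P %*% yObs)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cX))) + sum(yObs * Py))
  list(ll = ll, P = P, Py = Py)
}

#' Evaluate the REML log-likelihood of a model variant
#'
#' Returns -0.5 * (log|V| + log|X'V^-1 X| + y'Py) with
#' P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1. The additive constant
#' (-(n-p)/2 log 2pi) is omitted, so likelihood-ratio statistics are
#' unaffected by the convention.
#'
#' @param spec an \linkS4class{RNModelSpec}.
#' @param theta named parameter vector covering the spec's free
#'   parameters.
#' @param data list with \code{y} (phenotype), \code{A} (GRM or matrix),
#'   \code{c} (covariate, where the spec needs one), optional \code{X}
#'   (fixed-effect design; default intercept per trait) and optional
#'   \code{groups} (precomputed stratification).
#' @return the REML log-likelihood, or -Inf when V is not positive
#'   definite at theta.
#' @export
remlLogLik <- function(spec, theta, data) {
  prep <- .remlPrepare(spec, data)
  ll <- .remlLLOnly(prep$ctx, theta[spec@params$name], prep$yObs, prep$X)
  if (is.null(ll)) -Inf else ll
}

.defaultStart <- function(spec, yObs, ctx) {
  pars <- spec@params
  n <- ctx$n
  vy <- stats::var(yObs[1:n])
  theta <- numeric(nrow(pars)); names(theta) <- pars$name
  isVar <- pars$l == pars$r & pars$block != "yc"
  yyVar <- isVar & pars$block == "yy"
  theta[yyVar] <- vy / sum(yyVar)
  if (ctx$bivariate) {
    vc <- stats::var(yObs[n + 1:n])
    ccVar <- isVar & pars$block == "cc"
    theta[ccVar] <- vc / sum(ccVar)
  }
  theta
}

#' Fit a reaction norm family model by AI-REML
#'
#' Average-information REML with an expectation-maximisation warm-up:
#' the first \code{emSteps} iterations update the variance-type
#' parameters by the EM recursion (covariances held), after which full
#' AI quasi-Newton updates are taken with step-halving whenever a
#' proposal decreases the likelihood or leaves the positive-definite
#' cone. Parameters with bounds (the GCI-GREML interaction variance) are
#' projected and frozen while their gradient points outward; all other
#' components are unconstrained, so interaction variances may be
#' estimated negative under the null and likelihood-ratio statistics
#' retain their plain chi-square reference. Convergence is declared when
#' the likelihood gain drops below \code{tol} or no parameter moves by
#' more than 1e-6. Standard errors come from the inverse AI matrix at
#' the optimum. Non-convergence is reported through the flag, never as
#' an error, so replicate loops can count failures.
#'
#' @param spec an \linkS4class{RNModelSpec}.
#' @param data list with \code{y}, \code{A}, and (when needed) \code{c},
#'   optional \code{X} and \code{groups}; see \code{\link{remlLogLik}}.
#' @param start optional named starting vector; defaults to an equal
#'   split of the phenotypic variance over the free variances with zero
#'   covariances.
#' @param maxIter maximum number of iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param emSteps number of EM warm-up iterations.
#' @param minN minimum sample size accepted (variance-component fits on
#'   smaller samples are not meaningful; lower it deliberately for toy
#'   examples).
#' @return an \linkS4class{RNFit}.
#' @export
fitReml <- function(spec, data, start = NULL, maxIter = 100L, tol = 1e-4,
                    emSteps = 2L, minN = 50L) {
  prep <- .remlPrepare(spec, data)
  ctx <- prep$ctx; yObs <- prep$yObs; X <- prep$X
  if (ctx$n < minN)
    stop("sample size ", ctx$n, " below minimum ", minN)
  pars <- spec@params
  lower <- pars$lower
  theta <- if (is.null(start)) .defaultStart(spec, yObs, ctx) else {
    th <- numeric(nrow(pars)); names(th) <- pars$name
    th[names(start)[names(start) %in% pars$name]] <-
      start[names(start) %in% pars$name]
    th
  }
  theta <- pmax(theta, lower)
  core <- .remlCore(ctx, theta, yObs, X)
  if (is.null(core)) {  # fall back to a PD-safe start
    theta <- .defaultStart(spec, yObs, ctx)
    core <- .remlCore(ctx, theta, yObs, X)
    if (is.null(core)) stop("covariance not positive definite at start")
  }
  ll <- core$ll
  isVar <- pars$l == pars$r & pars$block != "yc"
  nTrait <- ctx$n
  converged <- FALSE
  AI <- NULL; grad <- NULL
  iter <- 0L
  dll <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    tr <- .cvTraces(ctx, core$P)
    W <- .cvMultW(ctx, core$Py)
    uDu <- drop(crossprod(W, core$Py))
    grad <- -0.5 * (tr - uDu)
    PW <- core$P %*% W
    AI <- 0.5 * crossprod(W, PW)
    atBound <- theta <= lower + 1e-12 & grad < 0
    if (converged) break  # exit with AI/grad refreshed at the optimum
    if (iter <= emSteps) {
      delta <- ifelse(isVar & !atBound & theta > 0,
                      2 * theta^2 * grad / nTrait, 0)
    } else {
      free <- !atBound
      delta <- numeric(length(theta))
      if (any(free)) {
        Af <- AI[free, free, drop = FALSE]
        ridge <- 0
        repeat {
          sol <- tryCatch(solve(Af + diag(ridge, nrow(Af)), grad[free]),
                          error = function(e) NULL)
          if (!is.null(sol) && all(is.finite(sol))) break
          ridge <- max(ridge * 10, 1e-8 * mean(diag(Af)), 1e-12)
        }
        delta[free] <- sol
      }
    }
    if (all(abs(delta) < 1e-10)) { converged <- TRUE; next }
    step <- 1
    accepted <- FALSE
    for (h in 1:15) {
      thNew <- pmax(theta + step * delta, lower)
      llNew <- .remlLLOnly(ctx, thNew, yObs, X)
      if (!is.null(llNew) && llNew >= ll - 1e-10) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- max(abs(grad)) < 1e-2; break }
    dll <- llNew - ll
    maxMove <- max(abs(thNew - theta))
    theta <- thNew
    coreNew <- .remlCore(ctx, theta, yObs, X)
    if (is.null(coreNew)) { converged <- FALSE; break }
    core <- coreNew; ll <- core$ll
    if (iter > emSteps && (dll < tol || maxMove < 1e-6))
      converged <- TRUE  # one more pass refreshes AI, then exits
  }
  atBound <- theta <= lower + 1e-12
  se <- rep(NA_real_, length(theta))
  if (!is.null(AI)) {
    freeIdx <- which(!atBound)
    if (length(freeIdx)) {
      Vcov <- tryCatch(solve(AI[freeIdx, freeIdx, drop = FALSE]),
                       error = function(e) NULL)
      if (!is.null(Vcov)) {
        d <- diag(Vcov)
        se[freeIdx] <- sqrt(pmax(d, 0))
      }
    }
  }
  names(se) <- pars$name
  names(theta) <- pars$name
  new("RNFit", estimates = theta, se = se, logLik = ll,
      nIter = iter, converged = converged,
      boundary = stats::setNames(atBound, pars$name), spec = spec)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Two-model-fit protocol: both hypotheses are fitted independently and
#' the statistic 2 * (logL1 - logL0), clamped at zero, is referred to a
#' chi-square with degrees of freedom equal to the difference in
#' free-parameter count (no boundary mixture correction).
#'
#' @param fit0 the null-model \linkS4class{RNFit}.
#' @param fit1 the alternative-model \linkS4class{RNFit}; its spec must
#'   nest fit0's.
#' @return an \linkS4class{LRTResult}; \code{valid} is FALSE when either
#'   fit did not converge.
#' @export
lrt <- function(fit0, fit1) {
  stopifnot(is(fit0, "RNFit"), is(fit1, "RNFit"))
  if (!isNested(fit0@spec, fit1@spec))
    stop("fit0's spec is not nested in fit1's spec")
  df <- nParams(fit1@spec) - nParams(fit0@spec)
  stat <- max(0, 2 * (fit1@logLik - fit0@logLik))
  new("LRTResult", statistic = stat, df = as.integer(df),
      pValue = stats::pchisq(stat, df = df, lower.tail = FALSE),
      valid = fit0@converged && fit1@converged)
}
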