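# Independent oracles and fixture builders. Everything here is computed
# from first principles (per-pair loops, error-contrast likelihood) and
# deliberately shares no code with the package internals it checks.

makeTestGRM <- function(n, m, seed = 1L) {
  computeGRM(simulateGenotypes(n, m, seed = seed))
}

# random parameter vector for a spec, with variances positive and
# covariances small enough that V stays positive definite
randomTheta <- function(spec, seed = 1L) {
  set.seed(seed)
  p <- spec@params
  isVar <- p$l == p$r & p$block != "yc"
  th <- ifelse(isVar, runif(nrow(p), 0.5, 1.5), runif(nrow(p), -0.2, 0.2))
  th <- pmax(th, p$lower)
  names(th) <- p$name
  th
}

# per-pair brute-force covariance, written entry by entry from the
# bivariate model displays; theta uses the package's parameter names
# but the assembly below is independent loops
bruteForceV <- function(spec, theta, A, cv = NULL, groups = NULL) {
  if (spec@variant == "RNM_MULTI") {
    Avs <- lapply(A, function(a) if (is(a, "GRM")) grmValues(a) else a)
    cm <- as.matrix(cv)
    n <- nrow(Avs[[1]])
    V <- matrix(0, n, n)
    for (j in seq_along(Avs)) for (i in 1:n) for (l in 1:n) {
      g <- function(nm) if (nm %in% names(theta)) theta[[nm]] else 0
      V[i, l] <- V[i, l] + Avs[[j]][i, l] *
        (g(sprintf("kv00_%d", j)) +
           g(sprintf("kv01_%d", j)) * (cm[i, j] + cm[l, j]) +
           g(sprintf("kv11_%d", j)) * cm[i, j] * cm[l, j])
    }
    diag(V) <- diag(V) + theta[["mv00"]]
    return(V)
  }
  Av <- if (is(A, "GRM")) grmValues(A) else A
  n <- nrow(Av)
  g <- function(nm) if (nm %in% names(theta)) theta[[nm]] else 0
  if (spec@covariate == "stratified") {
    if (is.null(groups)) groups <- stratifyCovariate(cv, spec@nGroups)
    cc <- groups$values[groups$labels]
    lab <- groups$labels
  } else {
    cc <- if (is.null(cv)) rep(0, n) else cv
    lab <- NULL
  }
  Vyy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    gen <- Av[i, j] * (g("kv00") + g("kv01") * (cc[i] + cc[j]) +
                         g("kv11") * cc[i] * cc[j]) +
      Av[i, j] * g("sg")
    if (!is.null(lab) && lab[i] == lab[j]) gen <- gen + Av[i, j] * g("sgxe")
    res <- 0
    if (i == j) {
      res <- g("mv00") + 2 * g("mv01") * cc[i] + g("mv11") * cc[i]^2 +
        g("se")
      if (!is.null(lab)) res <- res + g(sprintf("res_g%d", lab[i]))
    }
    Vyy[i, j] <- gen + res
  }
  if (!spec@bivariate) return(Vyy)
  Vyc <- matrix(0, n, n); Vcc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Vyc[i, j] <- Av[i, j] * (g("kc0") + g("kc1") * cc[i]) +
      (i == j) * (g("mc0") + g("mc1") * cc[i])
    Vcc[i, j] <- Av[i, j] * g("vb") + (i == j) * g("ve")
  }
  rbind(cbind(Vyy, Vyc), cbind(t(Vyc), Vcc))
}

# REML log-likelihood through the error-contrast definition: project onto
# a basis of the null space of X' and take the Gaussian log-density of the
# contrasts (drops a theta-independent constant relative to the package's
# convention, so comparisons are on differences)
contrastLogLik <- function(V, X, y) {
  n <- nrow(V)
  K <- qr.Q(qr(X), complete = TRUE)[, (ncol(X) + 1):n, drop = FALSE]
  M <- crossprod(K, V) %*% K
  z <- drop(crossprod(K, y))
  -0.5 * (determinant(M)$modulus[1] + drop(z %*% solve(M, z)))
}

# convenience: default fixed-effect design for a spec
designX <- function(spec, n) {
  if (spec@bivariate) rbind(cbind(rep(1, n), 0), cbind(0, rep(1, n)))
  else matrix(1, n, 1)
}

# observation vector a spec is fitted to (standardized covariate as the
# second trait for bivariate variants)
obsVector <- function(spec, y, cv) {
  if (spec@bivariate) c(y, standardizeCovariate(cv)) else y
}

allVariants <- c("GREML", "RNM_GC", "RNM_RC", "RNM_FULL", "MVGREML",
                 "MRNM_GC", "MRNM_RC", "MRNM_FULL", "RR_GREML",
                 "GCI_GREML")
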