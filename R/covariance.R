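#' Polynomial basis of a covariate
#'
#' Builds the n x (k+1) matrix with row i equal to (c_i^0, c_i^1, ...,
#' c_i^k): the first column is all ones and, for k >= 1, the second
#' column reproduces the covariate.
#'
#' @param c covariate vector (finite values).
#' @param k polynomial order (>= 0).
#' @return numeric matrix with k + 1 columns.
#' @examples
#' polynomialBasis(c(-1, 0, 2), 2)
#' @export
polynomialBasis <- function(c, k = 1L) {
  if (any(!is.finite(c))) stop("covariate values must be finite")
  if (k < 0) stop("polynomial order must be >= 0")
  outer(as.numeric(c), 0:k, `^`)
}

#' Centre and scale a covariate
#'
#' @param c covariate vector.
#' @return covariate standardized to mean zero and unit variance.
#' @export
standardizeCovariate <- function(c) {
  s <- stats::sd(c)
  if (s == 0) stop("covariate is constant; cannot standardize")
  (c - mean(c)) / s
}

#' Genetic covariance of a reaction norm model
#'
#' Entry (i, j) is A_ij times the reaction-norm kernel (Phi K_y Phi')_ij,
#' so the matrix reduces to A scaled by var(alpha0) when all interaction
#' terms vanish.
#'
#' @param A a \linkS4class{GRM} or plain symmetric matrix.
#' @param Ky symmetric (k+1) x (k+1) covariance of the genetic random
#'   regression coefficients.
#' @param Phi polynomial basis from \code{\link{polynomialBasis}}.
#' @return n x n matrix A * (Phi Ky Phi') (elementwise product).
#' @export
geneticCovariance <- function(A, Ky, Phi) {
  v <- if (is(A, "GRM")) A@values else A
  if (max(abs(Ky - t(Ky))) > 1e-12) stop("Ky must be symmetric")
  v * (Phi %*% Ky %*% t(Phi))
}

#' Residual covariance of a reaction norm model
#'
#' Residual effects are individual-specific, so the residual covariance
#' is diagonal with entries (Phi My Phi')_ii, e.g. m00 + 2 m01 c_i +
#' m11 c_i^2 at order 1.
#'
#' @param My symmetric (k+1) x (k+1) covariance of the residual random
#'   regression coefficients.
#' @param Phi polynomial basis.
#' @return n x n diagonal matrix.
#' @export
residualCovariance <- function(My, Phi) {
  if (max(abs(My - t(My))) > 1e-12) stop("My must be symmetric")
  d <- rowSums((Phi %*% My) * Phi)
  if (any(d <= 0))
    warning("non-positive residual variance at some covariate values")
  diag(d, nrow = nrow(Phi))
}

# ---- internal structured-covariance context -------------------------------
#
# Every model variant's covariance is linear in its parameters:
# V(theta) = sum_p theta_p D_p with fixed symmetric matrices D_p that are
# Hadamard products of a base matrix (A, I, the same-group mask S, or a
# group indicator) with polynomial outer products of the covariate. The
# context caches the base matrices and covariate powers so V, the trace
# terms tr(P D_p) and the products D_p u can all be formed in O(n^2).

.cvContext <- function(spec, A, c = NULL, groups = NULL) {
  if (spec@variant == "RNM_MULTI") {
    if (!is.list(A)) stop("RNM_MULTI needs a list of relationship matrices")
    Avs <- lapply(A, function(a) if (is(a, "GRM")) a@values else
      as.matrix(a))
    cm <- as.matrix(c)
    if (ncol(cm) != length(Avs))
      stop("need one covariate column per relationship matrix")
    n <- nrow(Avs[[1]])
    k <- spec@order
    bases <- Avs
    names(bases) <- sprintf("A%d", seq_along(Avs))
    phiList <- lapply(seq_len(ncol(cm)), function(j)
      polynomialBasis(cm[, j], max(k, 1L)))
    return(list(spec = spec, n = n, nObs = n, phi = phiList[[1]],
                phiList = phiList, bases = bases,
                diagBases = list(I = rep(1, n)),
                params = spec@params, bivariate = FALSE))
  }
  Av <- if (is(A, "GRM")) A@values else as.matrix(A)
  n <- nrow(Av)
  k <- spec@order
  if (spec@covariate == "stratified") {
    if (is.null(groups)) {
      if (is.null(c)) stop("stratified spec needs a covariate or groups")
      groups <- stratifyCovariate(c, spec@nGroups)
    }
    cg <- groups$values[groups$labels]       # group representative values
    phi <- cbind(rep(1, n), if (k >= 1) outer(cg, 1:k, `^`))
  } else {
    if (is.null(c)) c <- rep(0, n)
    phi <- polynomialBasis(c, max(k, 1L))
  }
  bases <- list(A = Av)
  if (any(spec@params$base == "S")) {
    lab <- groups$labels
    bases$S <- Av * outer(lab, lab, `==`)
  }
  gb <- grep("^G", unique(spec@params$base), value = TRUE)
  diagBases <- list(I = rep(1, n))
  for (g in gb)
    diagBases[[g]] <- as.numeric(groups$labels == as.integer(sub("G", "", g)))
  list(spec = spec, n = n, nObs = if (spec@bivariate) 2L * n else n,
       phi = phi, bases = bases, diagBases = diagBases,
       params = spec@params, bivariate = spec@bivariate)
}

.cvPhiCol <- function(ctx, e, base = "A") {
  if (!is.null(ctx$phiList) && grepl("^A[0-9]+$", base))
    ctx$phiList[[as.integer(sub("A", "", base))]][, e + 1L]
  else ctx$phi[, e + 1L]
}

# dense derivative matrix of one parameter (for exposition and testing)
.cvDense <- function(ctx, p) {
  par <- ctx$params[p, ]
  n <- ctx$n
  isDiag <- par$base %in% names(ctx$diagBases)
  if (par$block == "yy") {
    if (isDiag) {
      b <- ctx$diagBases[[par$base]]
      d <- b * .cvPhiCol(ctx, par$l, par$base) * .cvPhiCol(ctx, par$r, par$base) *
        (if (par$l != par$r) 2 else 1)
      D <- diag(d, n)
    } else {
      B <- ctx$bases[[par$base]]
      D <- B * outer(.cvPhiCol(ctx, par$l, par$base), .cvPhiCol(ctx, par$r, par$base))
      if (par$l != par$r) D <- D + t(D)
    }
    if (!ctx$bivariate) return(D)
    out <- matrix(0, 2 * n, 2 * n); out[1:n, 1:n] <- D
    return(out)
  }
  out <- matrix(0, 2 * n, 2 * n)
  if (par$block == "cc") {
    out[n + 1:n, n + 1:n] <- if (isDiag) diag(ctx$diagBases[[par$base]], n)
      else ctx$bases[[par$base]]
    return(out)
  }
  # yc block: upper block U = diag(phi_l) %*% B  (trait side scaled)
  U <- if (isDiag) diag(.cvPhiCol(ctx, par$l, par$base) * ctx$diagBases[[par$base]], n)
    else .cvPhiCol(ctx, par$l, par$base) * ctx$bases[[par$base]]
  out[1:n, n + 1:n] <- U
  out[n + 1:n, 1:n] <- t(U)
  out
}

# V(theta) as a dense matrix
.cvV <- function(ctx, theta) {
  n <- ctx$n
  pars <- ctx$params
  theta <- theta[pars$name]
  Vyy <- matrix(0, n, n); dyy <- rep(0, n)
  Vyc <- NULL; Vcc <- NULL; dcc <- NULL
  if (ctx$bivariate) { Vyc <- matrix(0, n, n); Vcc <- matrix(0, n, n)
                       dcc <- rep(0, n) }
  for (p in seq_len(nrow(pars))) {
    par <- pars[p, ]; th <- theta[p]
    if (th == 0) next
    isDiag <- par$base %in% names(ctx$diagBases)
    if (par$block == "yy") {
      if (isDiag) {
        dyy <- dyy + th * ctx$diagBases[[par$base]] *
          .cvPhiCol(ctx, par$l, par$base) * .cvPhiCol(ctx, par$r, par$base) *
          (if (par$l != par$r) 2 else 1)
      } else {
        M <- ctx$bases[[par$base]] *
          outer(.cvPhiCol(ctx, par$l, par$base), .cvPhiCol(ctx, par$r, par$base))
        Vyy <- Vyy + th * (if (par$l != par$r) M + t(M) else M)
      }
    } else if (par$block == "cc") {
      if (isDiag) dcc <- dcc + th * ctx$diagBases[[par$base]]
      else Vcc <- Vcc + th * ctx$bases[[par$base]]
    } else {
      if (isDiag) {
        idx <- cbind(1:n, 1:n)
        Vyc[idx] <- Vyc[idx] + th * .cvPhiCol(ctx, par$l, par$base) *
          ctx$diagBases[[par$base]]
      } else {
        Vyc <- Vyc + th * (.cvPhiCol(ctx, par$l, par$base) * ctx$bases[[par$base]])
      }
    }
  }
  diag(Vyy) <- diag(Vyy) + dyy
  if (!ctx$bivariate) return(Vyy)
  diag(Vcc) <- diag(Vcc) + dcc
  rbind(cbind(Vyy, Vyc), cbind(t(Vyc), Vcc))
}

# tr(P D_p) for every parameter, given dense symmetric P
.cvTraces <- function(ctx, P) {
  n <- ctx$n
  pars <- ctx$params
  Pyy <- P[1:n, 1:n, drop = FALSE]
  dPyy <- diag(Pyy)
  had <- list()  # Hadamard caches per (block, base)
  if (ctx$bivariate) {
    Pyc <- P[1:n, n + 1:n, drop = FALSE]
    Pcc <- P[n + 1:n, n + 1:n, drop = FALSE]
    dPyc <- diag(Pyc); dPcc <- diag(Pcc)
  }
  getHad <- function(block, base) {
    key <- paste(block, base)
    if (is.null(had[[key]])) {
      Pb <- if (block == "yy") Pyy else if (block == "yc") Pyc else Pcc
      had[[key]] <<- Pb * ctx$bases[[base]]
    }
    had[[key]]
  }
  out <- numeric(nrow(pars))
  for (p in seq_len(nrow(pars))) {
    par <- pars[p, ]
    isDiag <- par$base %in% names(ctx$diagBases)
    out[p] <- if (par$block == "yy") {
      if (isDiag) {
        sum(dPyy * ctx$diagBases[[par$base]] * .cvPhiCol(ctx, par$l, par$base) *
              .cvPhiCol(ctx, par$r, par$base)) * (if (par$l != par$r) 2 else 1)
      } else {
        M <- getHad("yy", par$base)
        v <- drop(crossprod(.cvPhiCol(ctx, par$l, par$base),
                            M %*% .cvPhiCol(ctx, par$r, par$base)))
        if (par$l != par$r) 2 * v else v
      }
    } else if (par$block == "cc") {
      if (isDiag) sum(dPcc * ctx$diagBases[[par$base]])
      else sum(getHad("cc", par$base))
    } else {
      if (isDiag) 2 * sum(dPyc * .cvPhiCol(ctx, par$l, par$base) *
                            ctx$diagBases[[par$base]])
      else 2 * sum(.cvPhiCol(ctx, par$l, par$base) * rowSums(getHad("yc", par$base)))
    }
  }
  names(out) <- pars$name
  out
}

# matrix whose column p is D_p %*% u
.cvMultW <- function(ctx, u) {
  n <- ctx$n
  pars <- ctx$params
  u1 <- u[1:n]
  u2 <- if (ctx$bivariate) u[n + 1:n] else NULL
  W <- matrix(0, length(u), nrow(pars))
  for (p in seq_len(nrow(pars))) {
    par <- pars[p, ]
    isDiag <- par$base %in% names(ctx$diagBases)
    if (par$block == "yy") {
      if (isDiag) {
        w1 <- ctx$diagBases[[par$base]] * .cvPhiCol(ctx, par$l, par$base) *
          .cvPhiCol(ctx, par$r, par$base) * u1 * (if (par$l != par$r) 2 else 1)
      } else {
        B <- ctx$bases[[par$base]]
        w1 <- .cvPhiCol(ctx, par$l, par$base) * drop(B %*% (.cvPhiCol(ctx, par$r, par$base) * u1))
        if (par$l != par$r)
          w1 <- w1 + .cvPhiCol(ctx, par$r, par$base) *
            drop(B %*% (.cvPhiCol(ctx, par$l, par$base) * u1))
      }
      W[1:n, p] <- w1
    } else if (par$block == "cc") {
      W[n + 1:n, p] <- if (isDiag) ctx$diagBases[[par$base]] * u2
        else drop(ctx$bases[[par$base]] %*% u2)
    } else {
      fl <- .cvPhiCol(ctx, par$l, par$base)
      if (isDiag) {
        b <- ctx$diagBases[[par$base]]
        W[1:n, p] <- fl * b * u2
        W[n + 1:n, p] <- fl * b * u1
      } else {
        B <- ctx$bases[[par$base]]
        W[1:n, p] <- fl * drop(B %*% u2)
        W[n + 1:n, p] <- drop(B %*% (fl * u1))
      }
    }
  }
  W
}

#' Assemble the joint covariance of a model variant
#'
#' Builds the full observation covariance V(theta) of the given spec -
#' n x n for univariate variants, 2n x 2n (y stacked above c) for
#' bivariate ones - together with the derivative matrix dV/dtheta_p of
#' every free parameter. V is linear in the parameters, so each
#' derivative is a fixed Hadamard/diagonal pattern independent of theta.
#'
#' @param spec an \linkS4class{RNModelSpec}.
#' @param theta named numeric vector covering the spec's free parameters.
#' @param A a \linkS4class{GRM} or plain symmetric matrix.
#' @param c covariate vector (raw; standardized internally when the spec
#'   says so).
#' @param groups optional precomputed stratification from
#'   \code{\link{stratifyCovariate}} for the stratified variants.
#' @return list with elements \code{V} (dense symmetric matrix) and
#'   \code{derivatives} (named list of dense symmetric matrices).
#' @export
jointCovariance <- function(spec, theta, A, c = NULL, groups = NULL) {
  stopifnot(is(spec, "RNModelSpec"))
  missingPar <- setdiff(spec@params$name, names(theta))
  if (length(missingPar))
    stop("theta misses parameters: ", paste(missingPar, collapse = ", "))
  if (!is.null(c) && spec@standardize)
    c <- if (is.matrix(c)) apply(c, 2, standardizeCovariate)
      else standardizeCovariate(c)
  ctx <- .cvContext(spec, A, c, groups)
  derivs <- lapply(seq_len(nrow(ctx$params)), function(p) .cvDense(ctx, p))
  names(derivs) <- ctx$params$name
  list(V = .cvV(ctx, theta[spec@params$name]), derivatives = derivs)
}
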