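test_that("REML likelihood is flat along confounded components when A = I", {
  spec <- makeModel("GREML")
  data <- list(y = rnorm(30, sd = 1.4), A = diag(30))
  l1 <- remlLogLik(spec, c(kv00 = 1, mv00 = 1), data)
  l2 <- remlLogLik(spec, c(kv00 = 0.5, mv00 = 1.5), data)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("likelihood differences match the error-contrast oracle on every variant", {
  A <- makeTestGRM(30, 120, seed = 29)
  set.seed(42)
  cv <- rnorm(30)
  y <- rnorm(30, sd = 1.5)
  for (variant in allVariants) {
    spec <- makeModel(variant, nGroups = 3L, standardize = FALSE)
    th1 <- randomTheta(spec, seed = 1)
    th2 <- randomTheta(spec, seed = 2)
    data <- list(y = y, c = cv, A = A)
    d <- remlLogLik(spec, th1, data) - remlLogLik(spec, th2, data)
    X <- designX(spec, 30)
    yo <- if (spec@bivariate) c(y, cv) else y
    dOra <- contrastLogLik(bruteForceV(spec, th1, A, cv), X, yo) -
      contrastLogLik(bruteForceV(spec, th2, A, cv), X, yo)
    expect_equal(d, dOra, tolerance = 1e-8)
  }
})

test_that("fitted maximum agrees with direct optimization of the oracle likelihood", {
  A <- makeTestGRM(40, 200, seed = 31)
  L <- grmSquareRoot(A)
  sim <- simulateFull(L, simPreset("gc_power"), seed = 5, factor = TRUE)
  for (variant in c("GREML", "RNM_GC")) {
    spec <- makeModel(variant, standardize = FALSE)
    fit <- fitReml(spec, list(y = sim@y, c = sim@c, A = A), minN = 10)
    expect_true(isConverged(fit))
    X <- designX(spec, 40)
    negOra <- function(th) {
      names(th) <- paramNames(spec)
      V <- bruteForceV(spec, th, A, sim@c)
      if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
        return(1e10)
      -contrastLogLik(V, X, sim@y)
    }
    opt <- optim(coef(fit) * 0 + 1, negOra, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    opt2 <- optim(coef(fit), negOra, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
    best <- min(opt$value, opt2$value)
    # compare on the common (contrast) scale
    achieved <- -negOra(coef(fit))
    expect_lt(abs(achieved - (-best)), 1e-3)
    expect_gte(achieved, -best - 1e-3)
  }
})

test_that("REML estimates are scale equivariant", {
  A <- makeTestGRM(150, 600, seed = 37)
  sim <- simulateFull(grmSquareRoot(A), simPreset("null"), seed = 9,
                      factor = TRUE)
  spec <- makeModel("GREML")
  f1 <- fitReml(spec, list(y = sim@y, A = A))
  f2 <- fitReml(spec, list(y = 2 * sim@y, A = A))
  expect_equal(coef(f2), 4 * coef(f1), tolerance = 0.02)
  expect_true(isConverged(f1) && isConverged(f2))
})

test_that("fits are invariant to permuting individuals", {
  A <- makeTestGRM(120, 500, seed = 41)
  sim <- simulateFull(grmSquareRoot(A), simPreset("gc_power"), seed = 3,
                      factor = TRUE)
  spec <- makeModel("RNM_GC")
  f1 <- fitReml(spec, list(y = sim@y, c = sim@c, A = A))
  set.seed(8); pp <- sample(120)
  f2 <- fitReml(spec, list(y = sim@y[pp], c = sim@c[pp],
                           A = grmValues(A)[pp, pp]))
  expect_equal(logLik(f2), logLik(f1), tolerance = 1e-3)
  expect_equal(coef(f2), coef(f1), tolerance = 0.01)
})

test_that("likelihood-ratio mechanics follow the chi-square reference", {
  spec0 <- makeModel("GREML"); spec1 <- makeModel("RNM_FULL")
  mkFit <- function(spec, ll, conv = TRUE) {
    th <- setNames(rep(1, nParams(spec)), paramNames(spec))
    new("RNFit", estimates = th, se = th * 0, logLik = ll,
        nIter = 1L, converged = conv,
        boundary = setNames(rep(FALSE, nParams(spec)), paramNames(spec)),
        spec = spec)
  }
  t0 <- lrt(mkFit(spec0, -100), mkFit(spec1, -100))
  expect_equal(t0@statistic, 0)
  expect_equal(t0@pValue, 1)
  expect_identical(t0@df, 4L)  # adds cov(a0,a1), var(a1), m01, m11

  spec2 <- makeModel("RNM_GC")
  t1 <- lrt(mkFit(spec0, -103), mkFit(spec2, -100))
  expect_equal(t1@statistic, 6)
  expect_equal(t1@pValue, exp(-3), tolerance = 1e-10)

  # a likelihood drop is clamped at zero, unconverged fits are flagged
  t2 <- lrt(mkFit(spec0, -99.5), mkFit(spec2, -100, conv = FALSE))
  expect_equal(t2@statistic, 0)
  expect_false(t2@valid)
  expect_error(lrt(mkFit(spec1, -1), mkFit(spec2, -1)), "not nested")
})

test_that("GREML recovers simulated variance components on average", {
  A <- makeTestGRM(400, 2000, seed = 43)
  L <- grmSquareRoot(A)
  spec <- makeModel("GREML")
  est <- matrix(NA_real_, 12, 2)
  for (r in 1:12) {
    sim <- simulateFull(L, simPreset("null"), seed = 600 + r, factor = TRUE)
    f <- fitReml(spec, list(y = sim@y, A = A))
    if (isConverged(f)) est[r, ] <- coef(f)
  }
  mc <- apply(est, 2, sd, na.rm = TRUE) / sqrt(sum(!is.na(est[, 1])))
  mm <- colMeans(est, na.rm = TRUE)
  expect_lt(abs(mm[1] - 1), 2.6 * mc[1] + 0.02)
  expect_lt(abs(mm[2] - 1), 2.6 * mc[2] + 0.02)
})

test_that("alternative fits never fall below their nested null", {
  A <- makeTestGRM(150, 800, seed = 47)
  L <- grmSquareRoot(A)
  for (r in 1:6) {
    sim <- simulateFull(L, simPreset("gc_corr_null"), seed = 70 + r,
                        factor = TRUE)
    for (method in c("RNM", "RR_GREML", "GCI_GREML", "MRNM")) {
      pair <- modelPair(method)
      f0 <- fitReml(pair$h0, list(y = sim@y, c = sim@c, A = A))
      f1 <- fitReml(pair$h1, list(y = sim@y, c = sim@c, A = A),
                    start = mrnm:::.embedStart(f0, pair$h1))
      expect_gte(logLik(f1), logLik(f0) - 1e-6)
    }
  }
})

test_that("non-convergence is reported through the flag, not an error", {
  A <- makeTestGRM(80, 300, seed = 53)
  sim <- simulateFull(grmSquareRoot(A), simPreset("null"), seed = 1,
                      factor = TRUE)
  f <- fitReml(makeModel("GREML"), list(y = sim@y, A = A), maxIter = 1L,
               emSteps = 1L)
  expect_false(isConverged(f))
  expect_true(is.finite(logLik(f)))
})

test_that("small samples are refused unless the floor is lowered", {
  A <- makeTestGRM(20, 100, seed = 59)
  y <- rnorm(20)
  expect_error(fitReml(makeModel("GREML"), list(y = y, A = A)),
               "below minimum")
  f <- fitReml(makeModel("GREML"), list(y = y, A = A), minN = 10)
  expect_s4_class(f, "RNFit")
})
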