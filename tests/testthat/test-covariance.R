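test_that("polynomialBasis builds powers of the covariate", {
  expect_equal(polynomialBasis(0.5, 1), matrix(c(1, 0.5), 1))
  expect_equal(polynomialBasis(c(3, -2, 7), 0), matrix(1, 3, 1))
  expect_equal(polynomialBasis(c(-1, 0, 2), 2),
               matrix(c(1, 1, 1, -1, 0, 2, 1, 0, 4), 3))
  expect_error(polynomialBasis(c(1, NA), 1), "finite")
  expect_error(polynomialBasis(1:3, -1), "order")
})

test_that("geneticCovariance reduces to A without interaction and matches the per-pair oracle", {
  A <- grmValues(makeTestGRM(5, 60, seed = 13))
  cv <- c(-1.2, 0.3, 0, 2.1, -0.4)
  Phi <- polynomialBasis(cv, 1)
  expect_equal(geneticCovariance(A, matrix(c(1, 0, 0, 0), 2), Phi), A)

  K <- matrix(c(1, 0.05, 0.05, 0.25), 2)
  # rows with zero covariate see only var(alpha0)
  G <- geneticCovariance(A, K, Phi)
  expect_equal(G[3, 3], A[3, 3])

  ora <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    ora[i, j] <- A[i, j] * (K[1, 1] + K[1, 2] * (cv[i] + cv[j]) +
                              K[2, 2] * cv[i] * cv[j])
  expect_lt(max(abs(G - ora)), 1e-12)
  expect_error(geneticCovariance(A, matrix(c(1, 0.2, 0, 1), 2), Phi),
               "symmetric")
})

test_that("residualCovariance is diagonal with the quadratic expansion", {
  My <- matrix(c(1, 0.05, 0.05, 0.42), 2)
  R <- residualCovariance(My, polynomialBasis(c(1, 0), 1))
  expect_equal(diag(R), c(1 + 0.10 + 0.42, 1))
  expect_equal(R[1, 2], 0)
  R0 <- residualCovariance(matrix(c(1, 0, 0, 0), 2),
                           polynomialBasis(c(5, -3), 1))
  expect_equal(R0, diag(2))
  expect_warning(residualCovariance(matrix(c(0.1, 0, 0, -1), 2),
                                    polynomialBasis(c(0, 3), 1)),
                 "non-positive")
})

test_that("model variants free the documented parameter counts", {
  expect_identical(nParams(makeModel("GREML")), 2L)
  expect_identical(nParams(makeModel("RNM_GC")), 4L)
  expect_identical(nParams(makeModel("RNM_FULL")), 6L)
  expect_identical(nParams(makeModel("MVGREML")), 6L)
  expect_identical(nParams(makeModel("MRNM_FULL")), 12L)
  expect_identical(nParams(makeModel("RR_GREML", order = 0)), 5L)
  expect_identical(nParams(makeModel("RR_GREML")), 7L)
  gci <- makeModel("GCI_GREML")
  expect_identical(nParams(gci), 3L)
  expect_equal(gci@params$lower[gci@params$name == "sgxe"], 0)
  expect_error(makeModel("NOT_A_MODEL"))
})

test_that("structured assembly equals the per-pair brute-force oracle on every variant", {
  A <- makeTestGRM(7, 80, seed = 17)
  set.seed(99)
  cv <- rnorm(7)
  for (variant in allVariants) {
    for (s in 1:3) {
      spec <- makeModel(variant, nGroups = 3L, standardize = FALSE)
      th <- randomTheta(spec, seed = 100 * s + match(variant, allVariants))
      jc <- jointCovariance(spec, th, A, cv)
      ora <- bruteForceV(spec, th, A, cv)
      expect_lt(max(abs(jc$V - ora)), 1e-12)
    }
  }
})

test_that("derivative matrices are theta-free, symmetric, and match finite differences", {
  A <- makeTestGRM(6, 50, seed = 19)
  cv <- rnorm(6)
  for (variant in c("RNM_FULL", "MRNM_FULL", "GCI_GREML")) {
    spec <- makeModel(variant, nGroups = 2L, standardize = FALSE)
    th <- randomTheta(spec, seed = 7)
    jc <- jointCovariance(spec, th, A, cv)
    th2 <- randomTheta(spec, seed = 8)
    jc2 <- jointCovariance(spec, th2, A, cv)
    for (p in paramNames(spec)) {
      D <- jc$derivatives[[p]]
      expect_lt(max(abs(D - t(D))), 1e-12)
      expect_lt(max(abs(D - jc2$derivatives[[p]])), 1e-12)  # constant in theta
      h <- 1e-3
      thp <- th; thp[p] <- thp[p] + h
      fd <- (jointCovariance(spec, thp, A, cv)$V - jc$V) / h
      expect_lt(max(abs(fd - D)), 1e-9)  # V is linear in theta
    }
  }
})

test_that("H1 covariance at the H0-constrained point reproduces the H0 covariance", {
  A <- makeTestGRM(6, 50, seed = 23)
  cv <- rnorm(6)
  pairs <- list(c("GREML", "RNM_GC"), c("GREML", "RNM_FULL"),
                c("RNM_GC", "RNM_FULL"), c("MVGREML", "MRNM_FULL"),
                c("MRNM_GC", "MRNM_FULL"))
  for (pr in pairs) {
    s0 <- makeModel(pr[1], standardize = FALSE)
    s1 <- makeModel(pr[2], standardize = FALSE)
    expect_true(isNested(s0, s1))
    th0 <- randomTheta(s0, seed = 31)
    th1 <- setNames(rep(0, nParams(s1)), paramNames(s1))
    th1[names(th0)] <- th0
    expect_lt(max(abs(jointCovariance(s1, th1, A, cv)$V -
                        jointCovariance(s0, th0, A, cv)$V)), 1e-12)
  }
  expect_false(isNested(makeModel("MRNM_FULL"), makeModel("RNM_FULL")))
  # an additive null nests inside the stratified alternatives too
  expect_true(isNested(makeModel("GREML"), makeModel("GCI_GREML")))
  expect_false(isNested(makeModel("RNM_GC"), makeModel("GCI_GREML")))
})

test_that("the multi-covariate variant assembles per-effect kernels and fits", {
  spec <- makeModel("RNM_MULTI", nEffects = 2L, standardize = FALSE)
  expect_identical(nParams(spec), 7L)  # 3 per effect + shared residual
  A1 <- makeTestGRM(6, 40, seed = 131); A2 <- makeTestGRM(6, 40, seed = 137)
  set.seed(20); cm <- cbind(rnorm(6), rnorm(6))
  th <- randomTheta(spec, seed = 21)
  jc <- jointCovariance(spec, th, list(A1, A2), cm)
  expect_lt(max(abs(jc$V - bruteForceV(spec, th, list(A1, A2), cm))),
            1e-12)

  # uncorrelated effects: zeroing effect 2 reduces to the single-effect model
  th2 <- th; th2[grepl("_2$", names(th2))] <- 0
  single <- makeModel("RNM_GC", standardize = FALSE)
  th1 <- c(kv00 = th[["kv00_1"]], kv01 = th[["kv01_1"]],
           kv11 = th[["kv11_1"]], mv00 = th[["mv00"]])
  expect_lt(max(abs(jointCovariance(spec, th2, list(A1, A2), cm)$V -
                      jointCovariance(single, th1, A1, cm[, 1])$V)), 1e-12)

  # the REML engine fits the multi-effect spec end to end
  A <- makeTestGRM(150, 600, seed = 139)
  sim <- simulateFull(A, simPreset("gc_power"), seed = 31)
  set.seed(32)
  cm2 <- cbind(sim@c, rnorm(150))
  f <- fitReml(spec, list(y = sim@y, c = cm2, A = list(A, A)), minN = 50)
  expect_s4_class(f, "RNFit")
  expect_true(is.finite(logLik(f)))
})

test_that("model specs serialize to text and back", {
  spec <- makeModel("GCI_GREML", nGroups = 5L)
  path <- file.path(tempdir(), "spec.txt")
  writeModelSpec(spec, path)
  spec2 <- readModelSpec(path)
  expect_identical(spec2@variant, spec@variant)
  expect_identical(spec2@params, spec@params)
  expect_identical(spec2@nGroups, spec@nGroups)
  expect_identical(spec2@bivariate, spec@bivariate)
})
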