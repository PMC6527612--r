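test_that("named designs carry the documented covariance structures", {
  d0 <- simPreset("null")
  expect_equal(d0@sigmaG, diag(c(1, 1, 0)), ignore_attr = TRUE)
  expect_equal(d0@sigmaR, diag(c(1, 1, 0)), ignore_attr = TRUE)

  d3 <- simPreset("gc_power")
  expect_equal(d3@sigmaG,
               matrix(c(1, 0, 0.05, 0, 1, 0, 0.05, 0, 0.25), 3),
               ignore_attr = TRUE)

  d4 <- simPreset("gc_corr_null")
  expect_equal(d4@sigmaG,
               matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 0), 3),
               ignore_attr = TRUE)
  expect_equal(d4@sigmaR[1, 2], 0.3)

  expect_error(new("SimulationDesign", sigmaG = diag(c(-1, 1, 1)),
                   sigmaR = diag(3), label = "bad"),
               "positive semidefinite")
})

test_that("independent unit effects give uncorrelated standard-normal draws", {
  n <- 4000
  eff <- drawCorrelatedEffects(n, diag(3), diag(3), seed = 3,
                               factor = TRUE)
  S <- cov(cbind(eff$alpha0, eff$beta, eff$alpha1))
  expect_lt(max(abs(S - diag(3))), 3 * sqrt(2 / n) + 0.01)
})

test_that("genetic correlation between trait and covariate effects is realized", {
  n <- 5000
  d4 <- simPreset("gc_corr_null")
  eff <- drawCorrelatedEffects(n, d4@sigmaG, d4@sigmaR, seed = 5,
                               factor = TRUE)
  expect_lt(abs(cor(eff$alpha0, eff$beta) - 0.5), 3 / sqrt(n) * 2)
  expect_lt(abs(cor(eff$tau0, eff$eps) - 0.3), 3 / sqrt(n) * 2)
})

test_that("effect draws realize the Kronecker covariance with the GRM", {
  # across replicates, cov(alpha0_i, alpha0_j) = SigmaG[1,1] * A_ij
  A <- grmValues(makeTestGRM(5, 40, seed = 61))
  L <- grmSquareRoot(A)
  nRep <- 2000
  draws <- matrix(NA_real_, nRep, 5)
  for (r in seq_len(nRep))
    draws[r, ] <- drawCorrelatedEffects(L, diag(c(1, 1, 0)),
                                        diag(c(1, 1, 0)), seed = 5000 + r,
                                        factor = TRUE)$alpha0
  S <- cov(draws)
  expect_lt(max(abs(S - A)), 6 / sqrt(nRep) * max(diag(A)))
})

test_that("phenotypes decompose exactly into their retained components", {
  A <- makeTestGRM(60, 100, seed = 67)
  sim <- simulateFull(A, simPreset("gc_grid", value = 0.5), seed = 2)
  cp <- sim@components
  expect_identical(sim@y, cp$alpha0 + cp$alpha1c + cp$tau0 + cp$tau1c)
  expect_identical(sim@c, cp$beta + cp$eps)
  expect_true(validObject(sim))
})

test_that("marginal moments match the closed forms of each design", {
  n <- 4000
  I <- n  # identity relationship: unrelated individuals
  # null: var(y) = 2, var(c) = 2, cov(y, c) = 0
  s0 <- simulateFull(I, simPreset("null"), seed = 11, factor = TRUE)
  expect_lt(abs(var(s0@y) - 2), 0.15)
  expect_lt(abs(var(s0@c) - 2), 0.15)
  expect_lt(abs(cov(s0@y, s0@c)), 0.15)

  # genetic interaction: var(alpha1 * c) = var(alpha1) * var(c) = 0.5,
  # so var(y) = 2.5 and the interaction shares are 20% (term) / 10%
  # (var(alpha1) / var(y))
  s3 <- simulateFull(I, simPreset("gc_power"), seed = 12, factor = TRUE)
  expect_lt(abs(var(s3@y) - 2.5), 0.2)
  share <- var(s3@components$alpha1c) / var(s3@y)
  expect_lt(abs(share - 0.2), 0.03)
  expect_lt(abs(0.25 / var(s3@y) - 0.1), 0.01)

  # var(alpha1) = 1: var(y) = 4, term share 50%, var(alpha1)/var(y) = 25%
  s5 <- simulateFull(I, simPreset("gc_grid", value = 1), seed = 13,
                     factor = TRUE)
  expect_lt(abs(var(s5@y) - 4), 0.35)
  expect_lt(abs(var(s5@components$alpha1c) / var(s5@y) - 0.5), 0.04)

  # correlation null: cov(y, c) = cov(alpha0, beta) + cov(tau0, eps) = 0.8
  s4 <- simulateFull(I, simPreset("gc_corr_null"), seed = 14, factor = TRUE)
  expect_lt(abs(cov(s4@y, s4@c) - 0.8), 0.15)
  expect_lt(abs(var(s4@y) - 2), 0.15)
})

test_that("residual interaction produces the quadratic conditional variance", {
  n <- 20000
  sim <- simulateRCCI(n, varTau1 = 0.25, covT0T1 = 0.05, seed = 15,
                      factor = TRUE)
  resid <- sim@components$tau0 + sim@components$tau1c
  bins <- cut(sim@c, quantile(sim@c, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    expected <- mean(1 + 0.1 * sim@c[idx] + 0.25 * sim@c[idx]^2)
    expect_lt(abs(var(resid[idx]) / expected - 1), 0.15)
  }
})

test_that("rcci without residual interaction reduces to the additive model", {
  A <- makeTestGRM(200, 800, seed = 71)
  sim <- simulateRCCI(A, varTau1 = 0, covT0T1 = 0, seed = 16)
  expect_identical(max(abs(sim@components$tau1c)), 0)
  f <- fitReml(makeModel("GREML"), list(y = sim@y, A = A))
  expect_true(isConverged(f))
  expect_lt(abs(sum(coef(f)) - var(sim@y)), 0.2)  # total variance preserved
})

test_that("gcci residual correlation is realized in the components", {
  sim <- simulateGCCI(5000, reCov = 0.3, varAlpha1 = 0, covA0A1 = 0,
                      seed = 17, factor = TRUE)
  expect_lt(abs(cor(sim@components$tau0, sim@components$eps) - 0.3), 0.05)
})

test_that("simulated replicates are reproducible and writable", {
  A <- makeTestGRM(60, 100, seed = 73)
  s1 <- simulateFull(A, simPreset("gc_power"), seed = 99)
  s2 <- simulateFull(A, simPreset("gc_power"), seed = 99)
  expect_identical(s1@y, s2@y)
  prefix <- file.path(tempdir(), "simout")
  writeSimulatedData(s1, sampleIds(A), prefix)
  ph <- readPheno(paste0(prefix, ".phen"))
  expect_equal(ph$value, s1@y, tolerance = 1e-9)
  truth <- readLines(paste0(prefix, ".truth"))
  expect_true(any(grepl("var\\(alpha1\\) = 0.25", truth)))
  expect_error(drawCorrelatedEffects(diag(4), diag(c(1, 1, -1)), diag(3),
                                     factor = TRUE),
               "positive semidefinite")
})
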