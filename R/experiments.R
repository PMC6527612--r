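# Replicated simulation experiments: type-I error, power and the
# residual-variance inflation of additive models.

# map a null fit's estimates onto the alternative spec's parameters by
# structural key, so the alternative fit starts from the null optimum
# (guaranteeing logL(H1) >= logL(H0) under monotone-accept iterations)
.embedStart <- function(fit0, spec1) {
  p0 <- fit0@spec@params; p1 <- spec1@params
  key <- function(p) paste(p$block, p$base, p$l, p$r)
  idx <- match(key(p0), key(p1))
  start <- numeric(nrow(p1)); names(start) <- p1$name
  start[idx[!is.na(idx)]] <- fit0@estimates[!is.na(idx)]
  start
}

#' Standard H0/H1 spec pairs for the interaction tests
#'
#' \describe{
#'   \item{RNM}{additive GREML null against the univariate reaction norm
#'     model with a genetic random regression on the covariate.}
#'   \item{RR_GREML}{stratified null (per-group residual variances)
#'     against the same plus a genetic random regression on the group
#'     value.}
#'   \item{GCI_GREML}{additive GREML null against the same-group
#'     interaction component with homogeneous residual variance and the
#'     interaction variance constrained non-negative.}
#'   \item{MRNM}{bivariate additive null (MVGREML, which already carries
#'     the genetic and residual trait-covariate covariances) against the
#'     bivariate reaction norm model.}
#' }
#'
#' @param method one of "RNM", "RR_GREML", "GCI_GREML", "MRNM".
#' @param nGroups strata count for the stratified methods.
#' @return list with elements \code{h0} and \code{h1}
#'   (\linkS4class{RNModelSpec}s).
#' @export
modelPair <- function(method = c("RNM", "RR_GREML", "GCI_GREML", "MRNM"),
                      nGroups = 4L) {
  method <- match.arg(method)
  switch(method,
    RNM = list(h0 = makeModel("GREML"), h1 = makeModel("RNM_GC")),
    RR_GREML = list(h0 = makeModel("RR_GREML", order = 0L,
                                   nGroups = nGroups),
                    h1 = makeModel("RR_GREML", order = 1L,
                                   nGroups = nGroups)),
    GCI_GREML = list(h0 = makeModel("GREML"),
                     h1 = makeModel("GCI_GREML", nGroups = nGroups)),
    MRNM = list(h0 = makeModel("MVGREML"), h1 = makeModel("MRNM_GC")))
}

# fit one H0/H1 pair on one dataset; H1 warm-started from the H0 optimum
.fitPair <- function(pair, y, cv, A, groups = NULL, ...) {
  data <- list(y = y, c = cv, A = A, groups = groups)
  fit0 <- fitReml(pair$h0, data, ...)
  fit1 <- fitReml(pair$h1, data, start = .embedStart(fit0, pair$h1), ...)
  test <- lrt(fit0, fit1)
  list(fit0 = fit0, fit1 = fit1, test = test)
}

.experimentHeader <- function(path, seed, label) {
  writeLines(c(sprintf("# mrnm %s", as.character(utils::packageVersion("mrnm"))),
               sprintf("# experiment %s", label),
               sprintf("# base seed %d", seed),
               sprintf("# date %s", format(Sys.time(), "%Y-%m-%d"))), path)
}

#' Run a replicated likelihood-ratio simulation experiment
#'
#' Simulates \code{nReps} phenotype/covariate replicates under the given
#' design over one fixed GRM (replicate r uses seed \code{seed + r}),
#' fits the H0/H1 pair on each, and summarises the LRT p-values.
#' Non-converged replicates are excluded from the rejection proportion
#' and counted. With a \code{checkpoint} path, per-replicate rows are
#' appended as they complete and a rerun resumes after the last finished
#' replicate.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param pair list with specs \code{h0}, \code{h1} (see
#'   \code{\link{modelPair}}).
#' @param A a \linkS4class{GRM} or plain matrix.
#' @param nReps number of replicates.
#' @param seed base seed.
#' @param alpha significance level for the rejection proportion.
#' @param checkpoint optional TSV path for resumable per-replicate rows.
#' @return an \linkS4class{ExperimentResult}; the replicate table keeps
#'   the p-value, LRT statistic, both convergence flags and the fitted
#'   genetic/residual variances.
#' @export
runLrtExperiment <- function(design, pair, A, nReps = 200L, seed = 1L,
                             alpha = 0.05, checkpoint = NULL) {
  L <- grmSquareRoot(A)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.table(checkpoint, header = TRUE, sep = "\t",
                              comment.char = "#")
  } else if (!is.null(checkpoint)) {
    .experimentHeader(checkpoint, seed, design@label)
    cat("rep\tp\tstat\tconv0\tconv1\tresid0\tresid1\tvarA1\n",
        file = checkpoint, append = TRUE)
  }
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    if (!is.null(done) && r %in% done$rep) {
      rows[[r]] <- done[done$rep == r, , drop = FALSE]
      next
    }
    sim <- simulateFull(L, design, seed = seed + r, factor = TRUE)
    res <- .fitPair(pair, sim@y, sim@c, A)
    e0 <- res$fit0@estimates; e1 <- res$fit1@estimates
    resid0 <- if ("mv00" %in% names(e0)) e0[["mv00"]] else
      if ("res_g1" %in% names(e0))
        mean(e0[grep("^res_g", names(e0))]) else e0[["se"]]
    resid1 <- if ("mv00" %in% names(e1)) e1[["mv00"]] else
      if ("res_g1" %in% names(e1))
        mean(e1[grep("^res_g", names(e1))]) else e1[["se"]]
    row <- data.frame(rep = r, p = res$test@pValue,
                      stat = res$test@statistic,
                      conv0 = res$fit0@converged,
                      conv1 = res$fit1@converged,
                      resid0 = resid0, resid1 = resid1,
                      varA1 = if ("kv11" %in% names(e1))
                        e1[["kv11"]] else NA_real_)
    rows[[r]] <- row
    if (!is.null(checkpoint))
      utils::write.table(row, checkpoint, append = TRUE, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$conv0 & tab$conv1
  new("ExperimentResult", replicates = tab,
      rejectionRate = mean(tab$p[ok] < alpha),
      lambda = lambdaMedian(tab$p[ok]),
      alpha = alpha, nExcluded = as.integer(sum(!ok)))
}

#' Type-I error experiment for an interaction test
#'
#' Replicates simulated under a null design (no interaction variance for
#' the tested component) are fitted with the H0/H1 pair; the rejection
#' proportion at \code{alpha} estimates the empirical type-I error.
#'
#' @inheritParams runLrtExperiment
#' @return an \linkS4class{ExperimentResult}.
#' @export
typeIErrorExperiment <- function(design, pair, A, nReps = 200L, seed = 1L,
                                 alpha = 0.05, checkpoint = NULL) {
  if (max(abs(design@sigmaG[3, 3]), abs(design@sigmaR[3, 3])) > 0)
    stop("type-I error design must have zero interaction variance")
  runLrtExperiment(design, pair, A, nReps, seed, alpha, checkpoint)
}

#' Power experiment for an interaction test
#'
#' As \code{\link{typeIErrorExperiment}} but under a design with nonzero
#' interaction truth; the rejection proportion estimates power.
#'
#' @inheritParams runLrtExperiment
#' @return an \linkS4class{ExperimentResult}.
#' @export
powerExperiment <- function(design, pair, A, nReps = 100L, seed = 1L,
                            alpha = 0.05, checkpoint = NULL) {
  runLrtExperiment(design, pair, A, nReps, seed, alpha, checkpoint)
}

#' Residual-variance inflation of the additive model under interaction
#'
#' For each interaction variance on the grid, simulates replicates under
#' the genotype-covariate (or residual-covariate) interaction design and
#' records the residual variance estimated by additive GREML
#' (y = alpha0 + e) and, optionally, by the matching reaction norm
#' model. The simulated true residual variance is 1, so the reported
#' means are directly the inflation folds (an interaction variance of
#' 0.25 adds 0.25 * var(c) = 0.5 to what the additive model calls
#' residual, a 1.5-fold inflation; 1 gives 3-fold).
#'
#' @param A a \linkS4class{GRM} or plain matrix.
#' @param varGrid grid of interaction variances.
#' @param nReps replicates per grid point.
#' @param seed base seed.
#' @param model "gc" for genetic interaction (fits RNM G-C), "rc" for
#'   residual interaction (fits RNM R-C).
#' @param fitRnm also fit the reaction norm model (slower).
#' @return data.frame with one row per grid point: mean GREML residual
#'   variance with 95 percent CI over replicates, and the RNM residual
#'   mean/CI when requested.
#' @export
inflationExperiment <- function(A, varGrid = c(0, 0.25, 0.5, 0.75, 1),
                                nReps = 100L, seed = 1L,
                                model = c("gc", "rc"), fitRnm = TRUE) {
  model <- match.arg(model)
  L <- grmSquareRoot(A)
  greml <- makeModel("GREML")
  rnm <- makeModel(if (model == "gc") "RNM_GC" else "RNM_RC")
  out <- NULL
  for (v in varGrid) {
    g <- r <- matrix(NA_real_, nReps, 2)  # residual, genetic
    rn <- matrix(NA_real_, nReps, 1)
    for (i in seq_len(nReps)) {
      # intercept/slope covariance 0.05 applies on the interacting part of
      # the grid; a zero interaction variance forces a zero covariance
      cv01 <- if (v > 0.0025) 0.05 else 0
      sim <- if (model == "gc")
        simulateGCCI(L, varAlpha1 = v, covA0A1 = cv01, seed = seed + i,
                     factor = TRUE)
      else
        simulateRCCI(L, varTau1 = v, covT0T1 = cv01, seed = seed + i,
                     factor = TRUE)
      f0 <- fitReml(greml, list(y = sim@y, A = A))
      if (f0@converged) g[i, ] <- f0@estimates[c("mv00", "kv00")]
      if (fitRnm) {
        f1 <- fitReml(rnm, list(y = sim@y, c = sim@c, A = A),
                      start = .embedStart(f0, rnm))
        if (f1@converged) rn[i, 1] <- f1@estimates["mv00"]
      }
    }
    ci <- function(x) {
      x <- x[!is.na(x)]
      stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    }
    row <- data.frame(interactionVar = v,
                      gremlResid = mean(g[, 1], na.rm = TRUE),
                      gremlResidCI = ci(g[, 1]),
                      gremlGenetic = mean(g[, 2], na.rm = TRUE),
                      trueResid = 1)
    row$rnmResid <- if (fitRnm) mean(rn[, 1], na.rm = TRUE) else NA_real_
    row$rnmResidCI <- if (fitRnm) ci(rn[, 1]) else NA_real_
    out <- rbind(out, row)
  }
  out
}

#' Wald test on the residual-variance difference between RNM and GREML
#'
#' Fits additive GREML and the full reaction norm model on the same
#' data, reports the difference of their residual-variance estimates
#' (RNM minus GREML), a delete-a-group jackknife standard error, and the
#' two-tailed Wald p-value. Jackknife groups are a seeded random
#' partition of individuals; each leave-one-group-out refit is
#' warm-started from the full-data optimum.
#'
#' @param y phenotype vector.
#' @param cv covariate vector.
#' @param A a \linkS4class{GRM} or plain matrix.
#' @param nJack number of jackknife groups.
#' @param seed seed for the group assignment.
#' @return list with difference, se, p, and the two fits.
#' @export
residualVarDiffTest <- function(y, cv, A, nJack = 50L, seed = 1L) {
  Av <- if (is(A, "GRM")) A@values else A
  n <- length(y)
  greml <- makeModel("GREML"); rnm <- makeModel("RNM_FULL")
  f0 <- fitReml(greml, list(y = y, A = Av))
  f1 <- fitReml(rnm, list(y = y, c = cv, A = Av),
                start = .embedStart(f0, rnm))
  diffFull <- f1@estimates[["mv00"]] - f0@estimates[["mv00"]]
  set.seed(seed)
  grp <- sample(rep_len(seq_len(nJack), n))
  d <- numeric(nJack)
  minN <- min(50L, n - max(tabulate(grp)))
  for (g in seq_len(nJack)) {
    keep <- grp != g
    j0 <- fitReml(greml, list(y = y[keep], A = Av[keep, keep]),
                  start = f0@estimates, minN = minN)
    j1 <- fitReml(rnm, list(y = y[keep], c = cv[keep],
                            A = Av[keep, keep]),
                  start = f1@estimates, minN = minN)
    d[g] <- j1@estimates[["mv00"]] - j0@estimates[["mv00"]]
  }
  se <- sqrt((nJack - 1) / nJack * sum((d - mean(d))^2))
  list(difference = diffFull, se = se,
       p = 2 * stats::pnorm(-abs(diffFull / se)),
       fitGreml = f0, fitRnm = f1)
}
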