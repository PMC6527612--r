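#' Upper-tail inverse-normal transform of a p-value
#'
#' Maps a p-value to the upper-tail standard-normal quantile, so the 0.05
#' significance level corresponds to the familiar 1.65 threshold.
#'
#' @param p probability in (0, 1].
#' @return numeric z-score(s).
#' @examples
#' pToZ(0.05)  # 1.645
#' @export
pToZ <- function(p) stats::qnorm(p, lower.tail = FALSE)

#' Median-based inflation statistic lambda
#'
#' Ratio of the observed median association test statistic to the
#' expected median under the null: p-values are mapped through the
#' chi-square(1) quantile and the median is divided by qchisq(0.5, 1)
#' (0.4549). A value near one indicates calibration.
#'
#' @param pvals vector of p-values.
#' @return numeric lambda.
#' @export
lambdaMedian <- function(pvals) {
  stats::median(stats::qchisq(pvals, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Combine p-values with Fisher's method
#'
#' X = -2 sum log(p_i) referred to a chi-square with 2 * length(pvals)
#' degrees of freedom. A single p-value is returned unchanged (the
#' chi-square(2) tail of -2 log p is p itself).
#'
#' @param pvals vector of p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisherMeta(c(0.5, 0.5))  # 0.597
#' @export
fisherMeta <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}

#' Rank-based inverse normal transformation
#'
#' Ranks (ties averaged) mapped through the normal quantile with the
#' Blom offset: qnorm((rank - 3/8) / (n + 1/4)). The output is invariant
#' to monotone transformations of the input.
#'
#' @param y numeric vector.
#' @return transformed vector with normal scores.
#' @export
rint <- function(y) {
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(y) + 1 / 4))
}

#' Stratify a covariate into discrete groups
#'
#' Default: quantile-based groups of near-equal size. Explicit
#' breakpoints are supported, e.g. a zero breakpoint so that
#' never-exposed individuals form their own stratum. A constant covariate
#' yields a single group with a warning.
#'
#' @param c covariate vector.
#' @param nGroups number of quantile groups (ignored when breakpoints
#'   are given).
#' @param breakpoints optional increasing interior cut points; groups are
#'   (-Inf, b1], (b1, b2], ..., (bk, Inf).
#' @return list with \code{labels} (integer group per individual) and
#'   \code{values} (per-group representative: the group mean of c).
#' @export
stratifyCovariate <- function(c, nGroups = 4L, breakpoints = NULL) {
  if (length(unique(c)) == 1L) {
    warning("covariate is constant; a single stratum is returned")
    return(list(labels = rep(1L, length(c)), values = c[1]))
  }
  if (is.null(breakpoints)) {
    qs <- stats::quantile(c, probs = seq(0, 1, length.out = nGroups + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    labels <- as.integer(cut(c, breaks = unique(qs), labels = FALSE))
  } else {
    labels <- as.integer(cut(c, breaks = c(-Inf, sort(breakpoints), Inf),
                             labels = FALSE))
  }
  values <- as.numeric(tapply(c, labels, mean))
  list(labels = labels, values = values)
}

#' Residuals of a phenotype after confounder adjustment
#'
#' Ordinary least-squares residuals of y on the confounder columns plus
#' an intercept; with no confounders the phenotype is simply centred.
#' The residuals are orthogonal to every confounder column.
#'
#' @param y response vector.
#' @param Xconf numeric matrix/data.frame of confounders (may be NULL or
#'   zero-column).
#' @return residual vector.
#' @export
adjustForConfounders <- function(y, Xconf = NULL) {
  if (is.null(Xconf) || NCOL(Xconf) == 0L) return(y - mean(y))
  stats::lm.fit(cbind(1, as.matrix(Xconf)), y)$residuals
}
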