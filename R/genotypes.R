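#' Simulate unlinked genotypes under Hardy-Weinberg proportions
#'
#' Each SNP is assigned an allele frequency drawn uniformly from
#' \code{mafRange}; genotype counts are the sum of two independent
#' Bernoulli(p) allele draws per individual, so Hardy-Weinberg proportions
#' hold by construction. No linkage disequilibrium is simulated: the
#' reaction norm models operate on the relationship matrix, for which the
#' marginal SNP frequencies are sufficient.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param mafRange length-2 numeric interval within (0, 0.5] from which
#'   allele frequencies are drawn.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- simulateGenotypes(100, 50, c(0.1, 0.5), seed = 1)
#' range(genoCounts(g))
#' @export
simulateGenotypes <- function(n, m, mafRange = c(0.01, 0.5), seed = 1L) {
  if (length(n) != 1L || length(m) != 1L || n < 2 || m < 1)
    stop("need n >= 2 individuals and m >= 1 SNPs")
  if (length(mafRange) != 2L || mafRange[1] > mafRange[2] ||
      mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("mafRange must be an interval within (0, 0.5]")
  set.seed(seed)
  p <- stats::runif(m, mafRange[1], mafRange[2])
  counts <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  new("GenotypeMatrix",
      counts = counts,
      ids = sprintf("FAM%05d_IND%05d", seq_len(n), seq_len(n)),
      snpIds = sprintf("snp%06d", seq_len(m)),
      freqs = colMeans(counts) / 2)
}

#' Compute the genomic relationship matrix
#'
#' Builds A = W W' / m' where W has entries
#' (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)), with p_j the sample allele
#' frequency of SNP j and m' the number of SNPs retained after the MAF
#' filter. Frequencies are always estimated from the analysed sample.
#' Monomorphic SNPs are dropped with a warning when \code{mafMin = 0}
#' would otherwise retain them (their standardization weight is
#' undefined). Missing genotypes are mean-imputed per SNP (zero on the
#' standardized scale).
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param mafMin minimum allele frequency; SNPs with frequency outside
#'   [mafMin, 1 - mafMin] are excluded.
#' @return a \linkS4class{GRM}.
#' @examples
#' A <- computeGRM(simulateGenotypes(50, 200, seed = 2))
#' mean(diag(grmValues(A)))
#' @export
computeGRM <- function(G, mafMin = 0.01) {
  stopifnot(is(G, "GenotypeMatrix"))
  cnt <- G@counts
  p <- colMeans(cnt, na.rm = TRUE) / 2
  keep <- p >= mafMin & p <= 1 - mafMin
  mono <- keep & (p == 0 | p == 1)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from the GRM")
    keep <- keep & !mono
  }
  if (!any(keep)) stop("no SNPs remain after MAF filtering")
  cnt <- cnt[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(cnt, 2L, 2 * p, "-")
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  A <- tcrossprod(W) / ncol(W)
  A <- (A + t(A)) / 2
  new("GRM", values = A, ids = G@ids, nSnps = ncol(W))
}

#' Prune related individuals from a GRM
#'
#' Greedy relatedness pruning: while any pair has a (signed) relatedness
#' entry above \code{threshold}, one member of a maximal pair is removed
#' at random (seeded). The retained submatrix has all off-diagonals at or
#' below the threshold. Pruning a pruned GRM changes nothing.
#'
#' @param A a \linkS4class{GRM}.
#' @param threshold positive relatedness cut-off (0.05 is conventional).
#' @param seed integer seed for the random within-pair choice.
#' @return character vector of retained individual identifiers.
#' @export
pruneRelated <- function(A, threshold = 0.05, seed = 1L) {
  stopifnot(is(A, "GRM"), threshold > 0)
  set.seed(seed)
  v <- A@values
  diag(v) <- -Inf
  alive <- rep(TRUE, nrow(v))
  repeat {
    vv <- v[alive, alive, drop = FALSE]
    if (all(vv <= threshold)) break
    idx <- which(alive)
    top <- which(vv == max(vv), arr.ind = TRUE)[1L, ]
    drop1 <- idx[top[sample.int(2L, 1L)]]
    alive[drop1] <- FALSE
  }
  A@ids[alive]
}

#' Symmetric square root of a GRM
#'
#' Eigendecomposition-based factor L with L L' = A; negative eigenvalues
#' of near-PSD sample GRMs are clipped at zero. Used by the simulator to
#' draw effect vectors with covariance proportional to A.
#'
#' @param A a \linkS4class{GRM} or a plain symmetric matrix.
#' @return an n x n matrix L with L L' = A (up to eigenvalue clipping).
#' @export
grmSquareRoot <- function(A) {
  v <- if (is(A, "GRM")) A@values else A
  eg <- eigen(v, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(ev) * t(eg$vectors))
}
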