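.par <- function(name, block, base, l = 0L, r = 0L, lower = -Inf)
  data.frame(name = name, block = block, base = base, l = as.integer(l),
             r = as.integer(r), lower = lower, stringsAsFactors = FALSE)

# Parameter naming: kv* entries of K_y (genetic regression coefficients),
# mv* entries of M_y (residual regression coefficients), kc*/mc* the
# K_yc/M_yc cross-covariances with the covariate's genetic/residual
# effect, vb/ve the covariate's own variances, res_g<k> per-group residual
# variances, sg/sgxe/se the GCI-GREML components.
.kyParams <- function(k) {
  out <- NULL
  for (q in 0:k) for (r in q:k)
    out <- rbind(out, .par(sprintf("kv%d%d", q, r), "yy", "A", q, r))
  out
}
.myParams <- function(k) {
  out <- NULL
  for (q in 0:k) for (r in q:k)
    out <- rbind(out, .par(sprintf("mv%d%d", q, r), "yy", "I", q, r))
  out
}
.kycParams <- function(k) {
  out <- NULL
  for (q in 0:k) out <- rbind(out, .par(sprintf("kc%d", q), "yc", "A", q))
  out
}
.mycParams <- function(k) {
  out <- NULL
  for (q in 0:k) out <- rbind(out, .par(sprintf("mc%d", q), "yc", "I", q))
  out
}
.covParams <- function() rbind(.par("vb", "cc", "A"), .par("ve", "cc", "I"))

#' Construct the model spec of a reaction norm family variant
#'
#' Returns the free-parameter mask of the requested model. Univariate
#' variants: \code{GREML} (additive: genetic + homogeneous residual),
#' \code{RNM_GC} (random regression of the genetic effect on the
#' covariate), \code{RNM_RC} (random regression of the residual),
#' \code{RNM_FULL} (both). Bivariate variants model y and the covariate c
#' jointly and add the covariate's own components plus the
#' genetic/residual cross-covariances: \code{MVGREML}, \code{MRNM_GC},
#' \code{MRNM_RC}, \code{MRNM_FULL}. The comparison estimators
#' \code{RR_GREML} (stratified covariate, per-group residual variances;
#' the H0 form is obtained with \code{order = 0}) and \code{GCI_GREML}
#' (same-group interaction component with homogeneous residual and a
#' non-negative interaction variance) carry the stratified-covariate
#' treatment.
#'
#' Every null model used in a likelihood-ratio test is nested in its
#' alternative: the H0 spec's parameters are a subset of the H1 spec's,
#' and setting the extra parameters to zero reproduces the H0 covariance.
#'
#' \code{RNM_MULTI} is the multiple-random-effect extension: each of
#' \code{nEffects} (relationship matrix, covariate) pairs carries its own
#' genetic random regression with per-effect coefficient covariance, the
#' random effects are assumed uncorrelated, and a single homogeneous
#' residual variance is estimated.
#'
#' @param variant model name (see Details).
#' @param order polynomial order k of the reaction norm basis (all
#'   shipped analyses use k = 1; \code{order = 0} gives the additive
#'   nulls).
#' @param nGroups number of covariate strata for the stratified variants.
#' @param standardize centre/scale the covariate before fitting.
#' @param nEffects number of (relationship matrix, covariate) pairs for
#'   \code{RNM_MULTI}.
#' @return an \linkS4class{RNModelSpec}.
#' @examples
#' nParams(makeModel("GREML"))      # 2
#' nParams(makeModel("MRNM_FULL"))  # 12
#' @export
makeModel <- function(variant = c("GREML", "RNM_GC", "RNM_RC", "RNM_FULL",
                                  "MVGREML", "MRNM_GC", "MRNM_RC",
                                  "MRNM_FULL", "RR_GREML", "GCI_GREML",
                                  "RNM_MULTI"),
                      order = 1L, nGroups = 4L, standardize = TRUE,
                      nEffects = 2L) {
  variant <- match.arg(variant)
  k <- as.integer(order)
  biv <- variant %in% c("MVGREML", "MRNM_GC", "MRNM_RC", "MRNM_FULL")
  covTreat <- if (variant %in% c("RR_GREML", "GCI_GREML"))
    "stratified" else "continuous"
  p <- switch(variant,
    GREML = rbind(.kyParams(0L), .myParams(0L)),
    RNM_GC = rbind(.kyParams(k), .myParams(0L)),
    RNM_RC = rbind(.kyParams(0L), .myParams(k)),
    RNM_FULL = rbind(.kyParams(k), .myParams(k)),
    MVGREML = rbind(.kyParams(0L), .myParams(0L), .kycParams(0L),
                    .mycParams(0L), .covParams()),
    MRNM_GC = rbind(.kyParams(k), .myParams(0L), .kycParams(k),
                    .mycParams(0L), .covParams()),
    MRNM_RC = rbind(.kyParams(0L), .myParams(k), .kycParams(0L),
                    .mycParams(k), .covParams()),
    MRNM_FULL = rbind(.kyParams(k), .myParams(k), .kycParams(k),
                      .mycParams(k), .covParams()),
    RR_GREML = {
      res <- NULL
      for (g in seq_len(nGroups))
        res <- rbind(res, .par(sprintf("res_g%d", g), "yy",
                               sprintf("G%d", g)))
      rbind(.kyParams(k), res)
    },
    GCI_GREML = rbind(.par("sg", "yy", "A"),
                      .par("sgxe", "yy", "S", lower = 0),
                      .par("se", "yy", "I")),
    RNM_MULTI = {
      out <- NULL
      for (j in seq_len(nEffects)) for (q in 0:k) for (r in q:k)
        out <- rbind(out, .par(sprintf("kv%d%d_%d", q, r, j), "yy",
                               sprintf("A%d", j), q, r))
      rbind(out, .par("mv00", "yy", "I"))
    })
  new("RNModelSpec", variant = variant, params = p, bivariate = biv,
      covariate = covTreat, nGroups = as.integer(nGroups), order = k,
      standardize = standardize)
}

#' Test whether one model spec is nested in another
#'
#' @param spec0 candidate null spec.
#' @param spec1 candidate alternative spec.
#' @return TRUE when spec0's free parameters are a subset of spec1's.
#' @export
isNested <- function(spec0, spec1) {
  stopifnot(is(spec0, "RNModelSpec"), is(spec1, "RNModelSpec"))
  p0 <- spec0@params; p1 <- spec1@params
  # the covariate representations must agree whenever the null actually
  # uses the covariate (an additive null like GREML nests inside both
  # continuous and stratified alternatives)
  usesCov <- any(p0$l > 0 | p0$r > 0 | p0$base != "A" & p0$base != "I")
  if (usesCov && spec0@covariate != spec1@covariate) return(FALSE)
  # nesting is structural: a parameter is identified by the covariance
  # pattern it multiplies, not by its label (GREML's genetic variance and
  # GCI-GREML's sg share the pattern A)
  key <- function(p) paste(p$block, p$base, p$l, p$r)
  all(key(p0) %in% key(p1))
}

#' Serialize a model spec to a plain-text key-value block
#'
#' @param spec an \linkS4class{RNModelSpec}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeModelSpec <- function(spec, path) {
  p <- spec@params
  lines <- c(
    paste("variant", spec@variant),
    paste("order", spec@order),
    paste("bivariate", spec@bivariate),
    paste("covariate", spec@covariate),
    paste("nGroups", spec@nGroups),
    paste("standardize", spec@standardize),
    sprintf("param %s %s %s %d %d %s", p$name, p$block, p$base, p$l, p$r,
            p$lower))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model spec from a plain-text key-value block
#'
#' @param path file written by \code{\link{writeModelSpec}}.
#' @return an \linkS4class{RNModelSpec}.
#' @export
readModelSpec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "[ \t]+")
  get1 <- function(key) {
    hit <- vapply(kv, function(x) x[1] == key, logical(1))
    kv[[which(hit)[1]]][2]
  }
  pl <- kv[vapply(kv, function(x) x[1] == "param", logical(1))]
  params <- do.call(rbind, lapply(pl, function(x)
    .par(x[2], x[3], x[4], as.integer(x[5]), as.integer(x[6]),
         as.numeric(x[7]))))
  new("RNModelSpec", variant = get1("variant"), params = params,
      bivariate = as.logical(get1("bivariate")),
      covariate = get1("covariate"),
      nGroups = as.integer(get1("nGroups")),
      order = as.integer(get1("order")),
      standardize = as.logical(get1("standardize")))
}
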