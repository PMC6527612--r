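#' Read a PLINK binary genotype trio (.bed/.bim/.fam)
#'
#' Reads the SNP-major .bed dialect (magic bytes 0x6c 0x1b, mode 0x01).
#' Genotypes are returned as counts of the .bim A1 allele: the two-bit
#' codes 00/10/11 map to 2/1/0 copies of A1 and 01 to missing.
#'
#' @param prefix path prefix; \code{prefix.bed/.bim/.fam} must exist.
#' @return a \linkS4class{GenotypeMatrix}; ids are "FID_IID" keys.
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  famTab <- utils::read.table(fam, colClasses = "character")
  bimTab <- utils::read.table(bim, colClasses = "character")
  n <- nrow(famTab); m <- nrow(bimTab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic bytes")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpr <- ceiling(n / 4)  # bytes per SNP record
  body <- raw[-(1:3)]
  if (length(body) != bpr * m) stop(".bed size inconsistent with .bim/.fam")
  # unpack two-bit codes: one column of bytes per SNP
  bytes <- matrix(as.integer(body), nrow = bpr, ncol = m)
  codes <- matrix(0L, nrow = 4 * bpr, ncol = m)
  for (k in 0:3)
    codes[seq.int(k + 1L, 4L * bpr, by = 4L), ] <- bytes %/% 4L^k %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  counts <- matrix(NA_integer_, n, m)
  counts[codes == 0L] <- 2L   # hom A1
  counts[codes == 2L] <- 1L   # het
  counts[codes == 3L] <- 0L   # hom A2
  new("GenotypeMatrix", counts = counts,
      ids = paste(famTab[[1]], famTab[[2]], sep = "_"),
      snpIds = bimTab[[2]],
      freqs = colMeans(counts, na.rm = TRUE) / 2)
}

#' Write a GenotypeMatrix as a PLINK binary trio
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writePlink <- function(G, prefix) {
  stopifnot(is(G, "GenotypeMatrix"))
  cnt <- G@counts; n <- nrow(cnt); m <- ncol(cnt)
  fid <- sub("_.*$", "", G@ids); iid <- sub("^[^_]*_", "", G@ids)
  utils::write.table(
    data.frame(fid, iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(1L, G@snpIds, 0, seq_len(m), "A", "G"),
    paste0(prefix, ".bim"), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  codeOf <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # counts of A1 -> two-bit code
  bpr <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4 * bpr, ncol = m)  # pad/missing = 01
  cc <- matrix(codeOf[as.character(cnt)], n, m)
  cc[is.na(cc)] <- 1L
  codes[seq_len(n), ] <- cc
  bytes <- matrix(0L, nrow = bpr, ncol = m)
  for (k in 0:3)
    bytes <- bytes + codes[seq.int(k + 1L, 4L * bpr, by = 4L), , drop = FALSE] * 4L^k
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

.grmPairOrder <- function(n) {
  i <- sequence(seq_len(n))                # column index within row
  j <- rep.int(seq_len(n), seq_len(n))     # row index
  cbind(j, i)
}

#' Read a GCTA binary GRM (.grm.bin/.grm.N.bin/.grm.id)
#'
#' The .grm.bin stores the lower triangle (including the diagonal) in
#' row-major pair order as 4-byte floats; .grm.N.bin stores the per-pair
#' SNP counts; .grm.id the FID/IID pairs.
#'
#' @param prefix path prefix (without the .grm.* extensions).
#' @return a \linkS4class{GRM}; \code{nSnps} is the rounded median pair count.
#' @export
readGRMBin <- function(prefix) {
  idTab <- utils::read.table(paste0(prefix, ".grm.id"),
                             colClasses = "character")
  n <- nrow(idTab); nPairs <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric",
                  n = nPairs, size = 4L)
  nsFile <- paste0(prefix, ".grm.N.bin")
  ns <- if (file.exists(nsFile))
    readBin(nsFile, "numeric", n = nPairs, size = 4L) else NA_real_
  A <- matrix(0, n, n)
  ord <- .grmPairOrder(n)
  A[ord] <- vals
  A[ord[, 2:1, drop = FALSE]] <- vals
  new("GRM", values = A, ids = paste(idTab[[1]], idTab[[2]], sep = "_"),
      nSnps = as.integer(round(stats::median(ns))))
}

#' Write a GRM in the GCTA binary dialect
#'
#' @param A a \linkS4class{GRM}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writeGRMBin <- function(A, prefix) {
  stopifnot(is(A, "GRM"))
  n <- nrow(A@values)
  ord <- .grmPairOrder(n)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(A@values[ord]), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(A@nSnps), n * (n + 1) / 2), con, size = 4L)
  close(con)
  fid <- sub("_.*$", "", A@ids); iid <- sub("^[^_]*_", "", A@ids)
  utils::write.table(data.frame(fid, iid), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a plain-text lower-triangle GRM
#'
#' Four whitespace-separated columns: index i, index j (j <= i), number
#' of SNPs, relatedness value; ids come from the matching .grm.id file.
#'
#' @param prefix path prefix; reads \code{prefix.grm.txt} and
#'   \code{prefix.grm.id}.
#' @return a \linkS4class{GRM}.
#' @export
readGRMText <- function(prefix) {
  idTab <- utils::read.table(paste0(prefix, ".grm.id"),
                             colClasses = "character")
  tab <- utils::read.table(paste0(prefix, ".grm.txt"))
  n <- nrow(idTab)
  A <- matrix(0, n, n)
  A[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
  A[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
  new("GRM", values = A, ids = paste(idTab[[1]], idTab[[2]], sep = "_"),
      nSnps = as.integer(round(stats::median(tab[[3]]))))
}

#' Write a GRM as plain-text lower triangle
#'
#' @param A a \linkS4class{GRM}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writeGRMText <- function(A, prefix) {
  stopifnot(is(A, "GRM"))
  n <- nrow(A@values)
  ord <- .grmPairOrder(n)
  utils::write.table(
    data.frame(ord[, 1], ord[, 2], A@nSnps,
               format(A@values[ord], digits = 10, trim = TRUE)),
    paste0(prefix, ".grm.txt"), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  fid <- sub("_.*$", "", A@ids); iid <- sub("^[^_]*_", "", A@ids)
  utils::write.table(data.frame(fid, iid), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a two-id phenotype/covariate file
#'
#' Whitespace-delimited FID, IID, value records (the PLINK phenotype
#' dialect). Both "NA" and -9 are read as missing.
#'
#' @param path file path.
#' @param missingValues values treated as missing (besides "NA").
#' @return data.frame with columns fid, iid, value and an id key column.
#' @export
readPheno <- function(path, missingValues = -9) {
  tab <- utils::read.table(path, colClasses = c("character", "character",
                                                "numeric"))
  names(tab) <- c("fid", "iid", "value")
  tab$value[tab$value %in% missingValues] <- NA_real_
  tab$id <- paste(tab$fid, tab$iid, sep = "_")
  tab
}

#' Write a two-id phenotype/covariate file
#'
#' @param ids character vector of "FID_IID" keys.
#' @param values numeric vector; NA written as "NA".
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePheno <- function(ids, values, path) {
  fid <- sub("_.*$", "", ids); iid <- sub("^[^_]*_", "", ids)
  utils::write.table(data.frame(fid, iid, format(values, digits = 10,
                                                 trim = TRUE)),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
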