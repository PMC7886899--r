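# Minimal PLINK-1 binary triplet (bed/bim/fam) writer and reader,
# SNP-major, for interchange with standard genetics tooling.
#
# 2-bit codes per individual, packed 4 to a byte, low bits first:
# 00 = hom A1 (dosage 2 of A1), 10 = het, 11 = hom A2, 01 = missing.
# We store dosage of A1, so dosage 2 -> 00, 1 -> 10, 0 -> 11.

#' Write genotypes in PLINK-1 binary layout
#'
#' @param x Dosage matrix (individuals x variants, values 0/1/2, NA allowed)
#'   or a `genotype_data`/`cohort` object (all variants are written).
#' @param prefix Output path prefix for `.bed`, `.bim`, `.fam`.
#' @param ids Individual ids (default from the object or row order).
#' @param variant_ids Variant names (default `var1..varM`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(x, prefix, ids = NULL, variant_ids = NULL) {
  if (inherits(x, "cohort")) {
    if (is.null(ids)) ids <- x$geno_ids
    chrom <- x$position$chrom; cm <- x$position$pos_cM
    x <- x$hapA + x$hapB
  } else if (inherits(x, "genotype_data")) {
    if (is.null(ids)) ids <- x$individual_ids
    chrom <- x$position$chrom; cm <- x$position$pos_cM
    x <- dosages(x)
  } else {
    chrom <- rep(1L, ncol(x)); cm <- seq_len(ncol(x))
  }
  n <- nrow(x); m <- ncol(x)
  if (is.null(ids)) ids <- seq_len(n)
  if (is.null(variant_ids)) variant_ids <- paste0("var", seq_len(m))

  code <- matrix(3L, n, m)          # dosage 0 -> 11 (3)
  code[x == 1L] <- 2L               # het -> 10
  code[x == 2L] <- 0L               # dosage 2 -> 00
  code[is.na(x)] <- 1L              # missing -> 01
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  b <- code[seq(1, nrow(code), by = 4), , drop = FALSE] +
    4L * code[seq(2, nrow(code), by = 4), , drop = FALSE] +
    16L * code[seq(3, nrow(code), by = 4), , drop = FALSE] +
    64L * code[seq(4, nrow(code), by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(b), con)
  close(con)

  utils::write.table(
    data.frame(chrom, variant_ids, cm, round(cm * 1e4), "A", "C"),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a PLINK-1 binary triplet
#'
#' @param prefix Path prefix (see [write_plink()]).
#' @return List with `dosages` (individuals x variants, NA for missing),
#'   `ids`, `variants` (the bim table).
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"))
  names(bim) <- c("chrom", "id", "cM", "bp", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  nbytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK-1 bed file")
  b <- as.integer(readBin(con, "raw", nbytes * m))
  close(con)
  q <- matrix(0L, 4L * nbytes, m)
  bm <- matrix(b, nbytes, m)
  q[seq(1, 4 * nbytes, by = 4), ] <- bm %% 4L
  q[seq(2, 4 * nbytes, by = 4), ] <- (bm %/% 4L) %% 4L
  q[seq(3, 4 * nbytes, by = 4), ] <- (bm %/% 16L) %% 4L
  q[seq(4, 4 * nbytes, by = 4), ] <- bm %/% 64L
  q <- q[seq_len(n), , drop = FALSE]
  d <- matrix(NA_integer_, n, m)
  d[q == 0L] <- 2L
  d[q == 2L] <- 1L
  d[q == 3L] <- 0L
  list(dosages = d, ids = fam[[2]], variants = bim)
}
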