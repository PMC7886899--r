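#' Genomic relationship matrix from allele dosages
#'
#' Computes the standard allele-frequency-weighted genomic relationship
#' `pi_ij = (1/m) sum_l (x_il - 2 p_l)(x_jl - 2 p_l) / (2 p_l (1 - p_l))`
#' over variants with `0 < p_l < 1`. Monomorphic variants are dropped with a
#' message. Frequencies default to those of the analysis sample.
#'
#' @param x Either a `genotype_data`/`cohort` object or an integer dosage
#'   matrix (individuals x variants).
#' @param freqs Optional allele frequencies; when NULL they are computed
#'   from `x` (half the column means of the dosages).
#' @param role For `genotype_data`/`cohort` input: which variant role to use
#'   (default "marker", mirroring a GRM built from genotyping-array SNPs).
#' @param ids Individual ids; defaults to those stored in `x` or row order.
#' @return An object of class `grm`: list with the symmetric `values`
#'   matrix, `ids`, `n_variants` used, and the `freqs` applied.
#' @export
compute_grm <- function(x, freqs = NULL, role = "marker", ids = NULL) {
  if (inherits(x, "cohort")) {
    if (is.null(ids)) ids <- x$geno_ids
    keep <- x$variant_role == role
    x <- (x$hapA + x$hapB)[, keep, drop = FALSE]
  } else if (inherits(x, "genotype_data")) {
    if (is.null(ids)) ids <- x$individual_ids
    x <- dosages(x, role = role)
  }
  if (is.null(ids)) ids <- seq_len(nrow(x))
  W <- grm_design(x, freqs)
  G <- tcrossprod(W) / attr(W, "n_variants")
  structure(list(values = G, ids = ids, n_variants = attr(W, "n_variants"),
                 freqs = attr(W, "freqs")),
            class = "grm")
}

# Centred and scaled dosage matrix W with G = W W' / m. Shared by the dense
# and streamed paths so both give identical numbers.
grm_design <- function(x, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(x) / 2
  ok <- freqs > 0 & freqs < 1
  if (!any(ok)) stop("all variants are monomorphic; cannot compute relationships")
  if (any(!ok)) message(sum(!ok), " monomorphic variant(s) dropped")
  W <- sweep(x[, ok, drop = FALSE], 2, 2 * freqs[ok])
  W <- sweep(W, 2, sqrt(2 * freqs[ok] * (1 - freqs[ok])), "/")
  attr(W, "n_variants") <- sum(ok)
  attr(W, "freqs") <- freqs[ok]
  W
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals,", x$n_variants, "variants\n")
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  mean diagonal %.4f; off-diagonal mean %.4g, range [%.3f, %.3f]\n",
              mean(diag(x$values)), mean(off), min(off), max(off)))
  invisible(x)
}

#' Enumerate pairs from a relationship matrix
#'
#' Emits every unordered pair once (i < j) with its relationship, flagging
#' parent-offspring pairs (known direct descendants have a different expected
#' covariance under assortative mating and are excluded from binning).
#'
#' @param grm A `grm` object.
#' @param pedigree Optional data.frame with columns `id`, `father`, `mother`.
#' @return A data.frame with columns i, j, id_i, id_j, pi, excluded, reason.
#' @export
extract_pairs <- function(grm, pedigree = NULL) {
  n <- length(grm$ids)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  pairs <- data.frame(i = i, j = j, id_i = grm$ids[i], id_j = grm$ids[j],
                      pi = grm$values[cbind(i, j)],
                      excluded = FALSE, reason = "")
  if (!is.null(pedigree)) {
    po <- parent_offspring_keys(pedigree)
    key <- pair_key(pairs$id_i, pairs$id_j)
    hit <- key %in% po
    pairs$excluded[hit] <- TRUE
    pairs$reason[hit] <- "parent-offspring"
  }
  pairs
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

parent_offspring_keys <- function(pedigree) {
  with(pedigree, c(
    pair_key(id[!is.na(father)], father[!is.na(father)]),
    pair_key(id[!is.na(mother)], mother[!is.na(mother)])))
}

#' Write a relationship matrix in GCTA binary layout
#'
#' Three files: `PREFIX.grm.bin` (little-endian 4-byte floats, lower triangle
#' including the diagonal, row by row), `PREFIX.grm.id` (two-column text,
#' family and individual id), and `PREFIX.grm.N.bin` (4-byte floats, number
#' of variants per element).
#'
#' @param grm A `grm` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  n <- length(grm$ids)
  lt <- grm$values[lower_triangle_index(n)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_variants), length(lt)), con, size = 4L,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$ids, grm$ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

#' Read a GCTA binary relationship matrix
#'
#' @param prefix Path prefix (see [write_grm()]).
#' @return A `grm` object; values carry the 4-byte float precision of the file.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  nel <- n * (n + 1L) / 2L
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lt <- readBin(con, "numeric", n = nel, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nv <- readBin(con, "numeric", n = nel, size = 4L, endian = "little")
  close(con)
  G <- matrix(0, n, n)
  idx <- lower_triangle_index(n)
  G[idx] <- lt
  G[idx[, c(2, 1)]] <- lt
  structure(list(values = G, ids = ids, n_variants = stats::median(nv),
                 freqs = NULL), class = "grm")
}

# Row-major lower-triangle (including diagonal) index matrix, GCTA order:
# (1,1), (2,1), (2,2), (3,1), ...
lower_triangle_index <- function(n) {
  i <- rep.int(seq_len(n), seq_len(n))
  j <- sequence(seq_len(n))
  cbind(i, j)
}
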