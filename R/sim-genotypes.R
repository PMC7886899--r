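#' Two-locus haplotype frequencies for a target r-squared
#'
#' Closed form for the haplotype frequencies of a causal variant (allele
#' frequency `p`) and its tagging marker (allele frequency `q`) with squared
#' allele correlation `r2`. The linkage-disequilibrium coefficient is
#' `D = sqrt(r2 * p(1-p) q(1-q))` (positive phase), so the four haplotype
#' frequencies are `pq + D`, `p(1-q) - D`, `(1-p)q - D`, `(1-p)(1-q) + D`.
#' `D` cannot exceed `min(p(1-q), (1-p)q)`, which bounds the attainable r2
#' between loci of unequal frequency.
#'
#' @param p,q Allele frequencies in (0, 1).
#' @param r2 Target squared correlation in \[0, 1\].
#' @return Named numeric vector `c(f11, f10, f01, f00)` where the first index
#'   is the causal allele and the second the marker allele.
#' @seealso [max_tagging_r2()]
#' @export
ld_haplotype_freqs <- function(p, q, r2) {
  stopifnot(p > 0, p < 1, q > 0, q < 1, r2 >= 0, r2 <= 1)
  r2max <- max_tagging_r2(p, q)
  if (r2 > r2max + 1e-12)
    stop(sprintf(paste0("tagging_r2 = %.4g unattainable for allele frequencies ",
                        "p = %.4g, q = %.4g: maximum attainable r2 is %.4g"),
                 r2, p, q, r2max))
  D <- sqrt(r2 * p * (1 - p) * q * (1 - q))
  f <- c(f11 = p * q + D, f10 = p * (1 - q) - D,
         f01 = (1 - p) * q - D, f00 = (1 - p) * (1 - q) + D)
  pmax(f, 0) / sum(pmax(f, 0))
}

#' Maximum attainable r-squared between two biallelic loci
#'
#' @param p,q Allele frequencies in (0, 1).
#' @return The upper bound on the squared allele correlation, reached when one
#'   haplotype class is absent.
#' @export
max_tagging_r2 <- function(p, q) {
  Dmax <- min(p * (1 - q), (1 - p) * q)
  Dmax^2 / (p * (1 - p) * q * (1 - q))
}

# Sex-averaged genetic lengths (cM) of the 22 human autosomes; ~3546 cM total.
.autosome_cM <- c(286.3, 268.8, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                  166.4, 181.1, 158.2, 174.7, 125.9, 120.8, 141.9, 134.0,
                  128.5, 117.2, 107.9, 108.3, 62.8, 74.1)

#' Default autosomal genetic map
#'
#' Lengths in centimorgans for the 22 human autosomes (sex-averaged,
#' totalling about 3546 cM). Used by the crossover simulator and as the
#' coordinate system variants are placed on.
#'
#' @return A data.frame with columns `chrom` and `cM`.
#' @export
default_genetic_map <- function() {
  data.frame(chrom = seq_along(.autosome_cM), cM = .autosome_cM)
}

# Tag-marker frequency compatible with the requested r2 to a causal variant
# of frequency p: sampled uniformly over the feasible part of the marker MAF
# range. Perfect LD (r2 = 1) forces the tag frequency to equal p.
draw_tag_freq <- function(p, range, r2) {
  if (r2 <= 0) return(runif(1, range[1], range[2]))
  if (r2 >= 1 - 1e-12) {
    if (p < range[1] - 1e-9 || p > range[2] + 1e-9)
      stop(sprintf(paste0("tagging_r2 = 1 requires a tag with frequency equal to ",
                          "the causal frequency %.3g, outside the marker MAF range ",
                          "[%.3g, %.3g]"), p, range[1], range[2]))
    return(p)
  }
  qs <- seq(range[1], range[2], length.out = 257)
  ok <- vapply(qs, function(q) max_tagging_r2(p, q) >= r2, TRUE)
  if (!any(ok))
    stop(sprintf(paste0("tagging_r2 = %.3g exceeds the maximum attainable r2 ",
                        "(%.3g) between a causal variant of frequency %.3g and any ",
                        "marker with frequency in [%.3g, %.3g]"),
                 r2, max(vapply(qs, max_tagging_r2, 0, p = p)), p,
                 range[1], range[2]))
  qf <- qs[ok]
  runif(1, min(qf), max(qf))
}

# Place n variants uniformly on the genome defined by `map`; returns a
# data.frame(chrom, pos_cM) sorted within chromosome.
place_variants <- function(n, map) {
  tot <- sum(map$cM)
  g <- sort(runif(n, 0, tot))
  cum <- c(0, cumsum(map$cM))
  chrom <- findInterval(g, cum, rightmost.closed = TRUE)
  chrom[chrom > nrow(map)] <- nrow(map)
  data.frame(chrom = map$chrom[chrom], pos_cM = g - cum[chrom])
}

#' Simulate founder genotypes with designated causal-tag LD
#'
#' Draws founder haplotypes for `n_causal` causal variants and `n_markers`
#' markers. Each causal variant is paired with one tagging marker; on each
#' haplotype the marker allele is sampled conditional on the causal allele
#' using the two-locus haplotype frequencies of [ld_haplotype_freqs()], so
#' the squared dosage correlation equals `tagging_r2` in expectation. A
#' causal variant and its tag share a genome position (complete linkage);
#' all other variants are placed independently on the autosomal map and are
#' unlinked in the founder population (linkage equilibrium).
#'
#' @param config A [sim_config()] object.
#' @param map Genetic map (defaults to [default_genetic_map()]).
#' @return An object of class `genotype_data`: a list with integer haplotype
#'   matrices `hapA`, `hapB` (individuals x variants, values 0/1),
#'   `variant_role` ("causal"/"marker"), `tag_of` (index of the tagged causal
#'   variant, NA otherwise), generating `allele_freq`, variant `position`
#'   (chrom, pos_cM) and `individual_ids`.
#' @export
simulate_founder_genotypes <- function(config, map = default_genetic_map()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  nc <- config$n_causal
  nm <- config$n_markers
  p_causal <- runif(nc, config$maf_causal_range[1], config$maf_causal_range[2])
  p_marker <- runif(nm, config$maf_marker_range[1], config$maf_marker_range[2])
  # tag frequencies are drawn from the feasible part of the marker range:
  # r2 between loci is bounded by min(p(1-q), (1-p)q)^2 / (p(1-p)q(1-q))
  p_marker[seq_len(nc)] <- vapply(p_causal, draw_tag_freq,
                                  0, range = config$maf_marker_range,
                                  r2 = config$tagging_r2)

  nv <- nc + nm
  draw_hap <- function() {
    h <- matrix(0L, n, nv)
    # causal alleles
    h[, seq_len(nc)] <- matrix(as.integer(runif(n * nc) < rep(p_causal, each = n)), n, nc)
    # tagging markers, conditional on the causal allele on the same haplotype
    for (l in seq_len(nc)) {
      f <- ld_haplotype_freqs(p_causal[l], p_marker[l], config$tagging_r2)
      p1 <- f["f11"] / (f["f11"] + f["f10"])  # P(marker = 1 | causal = 1)
      p0 <- f["f01"] / (f["f01"] + f["f00"])  # P(marker = 1 | causal = 0)
      pr <- ifelse(h[, l] == 1L, p1, p0)
      h[, nc + l] <- as.integer(runif(n) < pr)
    }
    # untagged markers
    if (nm > nc) {
      idx <- (nc + nc + 1L):nv
      pm <- p_marker[-seq_len(nc)]
      h[, idx] <- matrix(as.integer(runif(n * length(pm)) < rep(pm, each = n)),
                         n, length(pm))
    }
    h
  }
  hapA <- draw_hap()
  hapB <- draw_hap()

  pos <- place_variants(nv, map)
  pos[nc + seq_len(nc), ] <- pos[seq_len(nc), ]  # tag sits on its causal variant

  structure(list(
    hapA = hapA, hapB = hapB,
    variant_role = c(rep("causal", nc), rep("marker", nm)),
    tag_of = c(rep(NA_integer_, nc), seq_len(nc), rep(NA_integer_, nm - nc)),
    allele_freq = c(p_causal, p_marker),
    position = pos,
    individual_ids = seq_len(n),
    map = map
  ), class = "genotype_data")
}

#' Allele dosages of a genotype set
#'
#' @param geno A `genotype_data` object.
#' @param role Optional filter: "causal", "marker" or NULL (all variants).
#' @return Integer matrix of 0/1/2 dosages, individuals x variants.
#' @export
dosages <- function(geno, role = NULL) {
  x <- geno$hapA + geno$hapB
  if (!is.null(role)) x <- x[, geno$variant_role == role, drop = FALSE]
  x
}
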