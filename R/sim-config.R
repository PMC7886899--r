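#' Simulation configuration for a synthetic cohort
#'
#' Collects and validates every parameter of the multi-generation cohort
#' simulator: genetic architecture (number of causal variants and markers,
#' their allele-frequency ranges, the linkage disequilibrium between each
#' causal variant and its tagging marker), variance composition under random
#' mating (narrow-sense heritability `h2_rm`, shared environment `c2`,
#' additive-by-additive epistasis `v_aa`, the remainder being unique
#' environment), the target phenotypic correlation between mates
#' (`spousal_r`), and the pedigree layout (number of generations, sibship
#' size in the final generation, twin fractions).
#'
#' @param n_individuals Number of founders; interior generations keep this
#'   size (two offspring per couple), the final generation has
#'   `sibs_per_family` offspring per couple. Must be even.
#' @param n_causal Number of causal variants.
#' @param n_markers Number of marker variants used to build genomic
#'   relationships; the first `n_causal` of them are the tagging markers
#'   (one per causal variant).
#' @param maf_causal_range,maf_marker_range Length-2 numeric vectors in
#'   (0, 0.5] giving the ranges allele frequencies are drawn from.
#' @param tagging_r2 Target squared allele-dosage correlation between each
#'   causal variant and its tagging marker, in \[0, 1\]. Feasibility given the
#'   drawn allele frequencies is checked; see [max_tagging_r2()].
#' @param h2_rm Narrow-sense heritability under random mating (generation-0
#'   variance fraction of additive values).
#' @param c2 Shared-environment variance fraction (constant within family).
#' @param v_aa Additive-by-additive epistatic variance fraction.
#' @param spousal_r Target phenotypic correlation between mates, in \[-1, 1\].
#' @param n_generations Number of generations bred from the founders (>= 1).
#' @param sibs_per_family Full sibs per couple in the final generation.
#' @param interior_sibs Offspring per couple in interior generations
#'   (default 2, keeping the population size constant; 3 grows it by half
#'   each generation and densifies cousin/second-cousin classes).
#' @param twin_fractions Named numeric `c(mz = , dz = )`: fractions of
#'   final-generation families whose first two sibs are monozygotic
#'   (identical genotypes) or dizygotic twins.
#' @param keep_generations How many of the most recent generations retain
#'   genotypes (older generations keep pedigree and phenotype only).
#' @param seed Integer seed; all randomness in the simulator flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals,
                       n_causal = 300L,
                       n_markers = 1200L,
                       maf_causal_range = c(0.1, 0.5),
                       maf_marker_range = c(0.1, 0.5),
                       tagging_r2 = 1,
                       h2_rm = 0.6,
                       c2 = 0,
                       v_aa = 0,
                       spousal_r = 0,
                       n_generations = 10L,
                       sibs_per_family = 2L,
                       interior_sibs = 2L,
                       twin_fractions = c(mz = 0, dz = 0),
                       keep_generations = 2L,
                       seed = 1L) {
  stopifnot(n_individuals >= 4, n_individuals %% 2 == 0,
            n_causal >= 1, n_markers >= n_causal,
            n_generations >= 1, sibs_per_family >= 1, interior_sibs >= 1,
            keep_generations >= 1)
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || any(r > 0.5) || r[1] > r[2])
      stop(nm, " must be a pair of frequencies in (0, 0.5]")
  }
  chk_range(maf_causal_range, "maf_causal_range")
  chk_range(maf_marker_range, "maf_marker_range")
  if (tagging_r2 < 0 || tagging_r2 > 1) stop("tagging_r2 must be in [0, 1]")
  if (h2_rm < 0 || c2 < 0 || v_aa < 0 || h2_rm + c2 + v_aa > 1)
    stop("variance fractions must be non-negative with h2_rm + c2 + v_aa <= 1")
  if (abs(spousal_r) > 1) stop("spousal_r must be in [-1, 1]")
  if (is.null(names(twin_fractions))) names(twin_fractions) <- c("mz", "dz")
  if (sum(twin_fractions) > 1 || any(twin_fractions < 0))
    stop("twin fractions must be non-negative and sum to at most 1")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_causal = as.integer(n_causal),
    n_markers = as.integer(n_markers),
    maf_causal_range = maf_causal_range,
    maf_marker_range = maf_marker_range,
    tagging_r2 = tagging_r2,
    h2_rm = h2_rm, c2 = c2, v_aa = v_aa,
    spousal_r = spousal_r,
    n_generations = as.integer(n_generations),
    sibs_per_family = as.integer(sibs_per_family),
    interior_sibs = as.integer(interior_sibs),
    twin_fractions = twin_fractions,
    keep_generations = as.integer(keep_generations),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "founders,", x$n_causal, "causal +",
      x$n_markers, "marker variants,", x$n_generations, "generations\n")
  cat(sprintf("  h2_rm = %.2f, c2 = %.2f, v_aa = %.2f, spousal_r = %.2f, tagging_r2 = %.2f, seed = %d\n",
              x$h2_rm, x$c2, x$v_aa, x$spousal_r, x$tagging_r2, x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as key-value text
#'
#' Plain `key<TAB>value` lines mirroring the [sim_config()] field names;
#' vector fields are comma-separated. Round-trips exactly.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lines <- vapply(names(config), function(nm) {
    paste0(nm, "\t", paste(config[[nm]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- utils::read.table(path, sep = "\t", colClasses = "character")
  vals <- strsplit(kv[[2]], ",", fixed = TRUE)
  names(vals) <- kv[[1]]
  num <- lapply(vals, as.numeric)
  num$twin_fractions <- stats::setNames(num$twin_fractions, c("mz", "dz"))
  do.call(sim_config, num[setdiff(names(num), character(0))])
}
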