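# Shared configuration for the analysis scripts. Each numbered script is a
# thin driver over the package; they all rebuild the same deterministic
# cohort from this config, so they can be run independently and in order.

library(relspectrum)

dir.create("results", showWarnings = FALSE)

analysis_config <- function() {
  sim_config(
    n_individuals = 2000,          # founders; interior generations keep this size
    n_causal = 150, n_markers = 1500,
    maf_causal_range = c(0.1, 0.5), maf_marker_range = c(0.1, 0.5),
    tagging_r2 = 1,                # AE architecture with perfect tagging
    h2_rm = 0.7, c2 = 0, v_aa = 0,
    spousal_r = 0.24,              # height-like assortment
    n_generations = 6, sibs_per_family = 3,
    seed = 20240901
  )
}

analysis_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(analysis_config())
    cache
  }
})

# Prepared phenotype (within-sex standardised) for the analysis generations.
analysis_pheno <- function(co, generations = c(5, 6)) {
  ids <- analysis_ids(co, generations = generations)
  y <- standardize_within_sex(co$pheno$y_raw[match(ids, co$pheno$id)],
                              co$pedigree$sex[match(ids, co$pedigree$id)])
  list(ids = ids, y = stats::setNames(y, ids))
}

analysis_edges <- function() c(-0.08, -0.02, 0, 0.02, 0.05, 0.09, 0.175, 0.36, 0.7, 1.2)
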