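# Shared fixtures, built in code.

# Small random-mating cohort for structural tests.
small_cohort <- function(n = 400, h2 = 0.6, c2 = 0.1, v_aa = 0, spousal_r = 0,
                         gens = 2, sibs = 2, twins = c(mz = 0, dz = 0),
                         seed = 42, n_causal = 60, n_markers = 240, ...) {
  simulate_cohort(sim_config(
    n_individuals = n, n_causal = n_causal, n_markers = n_markers,
    h2_rm = h2, c2 = c2, v_aa = v_aa, spousal_r = spousal_r,
    n_generations = gens, sibs_per_family = sibs, twin_fractions = twins,
    seed = seed, ...))
}

# Prepared phenotype (plain standardisation) for a set of ids.
cohort_y <- function(co, ids) {
  y <- co$pheno$y_raw[match(ids, co$pheno$id)]
  sex <- co$pedigree$sex[match(ids, co$pedigree$id)]
  stats::setNames(standardize_within_sex(y, sex), ids)
}

# Independent weighted-least-squares oracle: solve the normal equations
# (X' W X) b = X' W y directly.
wls_oracle <- function(x, y, w, quadratic = FALSE) {
  X <- if (quadratic) cbind(1, x, x^2) else cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

# Brute-force GRM oracle: explicit double loop over pairs and variants.
grm_oracle <- function(x, freqs) {
  n <- nrow(x); m <- ncol(x)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(m)) {
      s <- s + (x[i, l] - 2 * freqs[l]) * (x[j, l] - 2 * freqs[l]) /
        (2 * freqs[l] * (1 - freqs[l]))
    }
    G[i, j] <- s / m
  }
  G
}

# Exact r2 implied by the conditional haplotype sampler: enumerate the
# two-locus haplotype frequencies it induces and compute the squared
# allele correlation.
sampler_r2_oracle <- function(p, q, r2) {
  f <- ld_haplotype_freqs(p, q, r2)
  p1 <- f[["f11"]] / p            # P(m=1 | c=1)
  p0 <- f[["f01"]] / (1 - p)      # P(m=1 | c=0)
  h11 <- p * p1; h10 <- p * (1 - p1); h01 <- (1 - p) * p0; h00 <- (1 - p) * (1 - p0)
  pm <- h11 + h01
  D <- h11 - p * pm
  D^2 / (p * (1 - p) * pm * (1 - pm))
}

# Sib-pair data generated directly from the additive + shared + unique
# model given realised IBD: cov(y1, y2) = ibd * s_a + s_c.
sim_sib_pairs <- function(n_pairs, s_a, s_c, s_e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ibd <- simulate_sib_ibd(n_pairs)
  y <- t(vapply(ibd, function(k) {
    S <- matrix(c(s_a + s_c + s_e, k * s_a + s_c,
                  k * s_a + s_c, s_a + s_c + s_e), 2, 2)
    L <- chol(S)
    drop(t(L) %*% rnorm(2))
  }, numeric(2)))
  data.frame(family = seq_len(n_pairs), id1 = paste0("a", seq_len(n_pairs)),
             id2 = paste0("b", seq_len(n_pairs)), ibd = ibd,
             y1 = y[, 1], y2 = y[, 2])
}
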