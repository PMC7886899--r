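test_that("two-locus haplotype frequencies reproduce the target r2 exactly", {
  for (case in list(c(0.2, 0.3, 0.4), c(0.05, 0.3, 0.10), c(0.4, 0.4, 0.9),
                    c(0.1, 0.1, 1))) {
    expect_equal(sampler_r2_oracle(case[1], case[2], case[3]), case[3],
                 tolerance = 1e-10)
  }
  f <- ld_haplotype_freqs(0.2, 0.3, 0.4)
  expect_equal(sum(f), 1)
  expect_true(all(f >= 0))
})

test_that("unattainable tagging r2 raises an error naming the bound", {
  # a rare causal variant cannot be tagged at r2 = 0.4 by a 30% marker
  expect_error(ld_haplotype_freqs(0.05, 0.30, 0.4), "maximum attainable")
  expect_lt(max_tagging_r2(0.05, 0.30), 0.13)
  expect_equal(max_tagging_r2(0.25, 0.25), 1)
  cfg <- sim_config(n_individuals = 50, n_causal = 5, n_markers = 10,
                    maf_causal_range = c(0.05, 0.05),
                    maf_marker_range = c(0.30, 0.30), tagging_r2 = 0.4)
  set.seed(1)
  expect_error(simulate_founder_genotypes(cfg), "maximum attainable")
})

test_that("perfect tagging with equal MAFs duplicates the causal dosages", {
  cfg <- sim_config(n_individuals = 200, n_causal = 10, n_markers = 20,
                    maf_causal_range = c(0.2, 0.4), maf_marker_range = c(0.2, 0.4),
                    tagging_r2 = 1)
  set.seed(2)
  g <- simulate_founder_genotypes(cfg)
  x <- dosages(g)
  expect_identical(x[, 1:10], x[, 11:20])
  # tags share the genome position of their causal variant
  expect_equal(g$position[11:20, ], g$position[1:10, ], ignore_attr = TRUE)
})

test_that("tagging r2 of zero gives uncorrelated causal and tag dosages", {
  cfg <- sim_config(n_individuals = 10000, n_causal = 4, n_markers = 8,
                    maf_causal_range = c(0.3, 0.4), maf_marker_range = c(0.3, 0.4),
                    tagging_r2 = 0)
  set.seed(3)
  g <- simulate_founder_genotypes(cfg)
  x <- dosages(g)
  for (l in 1:4) expect_lt(abs(cor(x[, l], x[, 4 + l])), 0.03)
})

test_that("empirical dosage r2 matches the target at an attainable setting", {
  # rare causal, common marker, target within the feasibility bound
  cfg <- sim_config(n_individuals = 20000, n_causal = 3, n_markers = 6,
                    maf_causal_range = c(0.05, 0.05),
                    maf_marker_range = c(0.25, 0.35), tagging_r2 = 0.10)
  set.seed(4)
  g <- simulate_founder_genotypes(cfg)
  x <- dosages(g)
  for (l in 1:3) {
    r2 <- cor(x[, l], x[, 3 + l])^2
    expect_equal(r2, 0.10, tolerance = 0.05)
  }
  # equal-frequency case at moderate r2
  cfg2 <- sim_config(n_individuals = 20000, n_causal = 3, n_markers = 6,
                     maf_causal_range = c(0.2, 0.2), maf_marker_range = c(0.2, 0.4),
                     tagging_r2 = 0.4)
  set.seed(5)
  g2 <- simulate_founder_genotypes(cfg2)
  x2 <- dosages(g2)
  for (l in 1:3) expect_equal(cor(x2[, l], x2[, 3 + l])^2, 0.4, tolerance = 0.05)
})

test_that("unlinked founder variants are independent", {
  cfg <- sim_config(n_individuals = 8000, n_causal = 2, n_markers = 30,
                    tagging_r2 = 0)
  set.seed(6)
  x <- dosages(simulate_founder_genotypes(cfg), role = "marker")
  cors <- cor(x[, 3:12])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
})

test_that("configuration files and the packaged genetic map round-trip", {
  cfg <- sim_config(n_individuals = 100, n_causal = 10, n_markers = 40,
                    h2_rm = 0.55, c2 = 0.1, spousal_r = 0.2,
                    twin_fractions = c(mz = 0.1, dz = 0.2), seed = 77)
  p <- file.path(tempdir(), "cfg.tsv")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  for (nm in names(cfg)) expect_equal(cfg2[[nm]], cfg[[nm]], ignore_attr = TRUE)

  mp <- read_genetic_map(system.file("extdata", "genetic_map_autosomes.tsv",
                                     package = "relspectrum"))
  expect_equal(nrow(mp), 22)
  expect_equal(mp$cM, default_genetic_map()$cM)
})
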