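test_that("the expected relative covariance evaluates the closed form", {
  expect_equal(am_expected_cov(1, 0, 0.6), 0.30)
  expect_equal(am_expected_cov(1, 0.24, 0.82), 0.4907, tolerance = 1e-4)
  d <- 0:12
  covs <- am_expected_cov(d, 0.3, 0.8)
  expect_true(all(diff(covs) < 0))
  expect_lt(covs[13], 0.01)
})

test_that("the log-linear fit inverts exactly on noiseless model bins", {
  h2 <- 0.82; r <- 0.24
  pi <- c(0.0625, 0.125, 0.25, 0.5)
  d <- log(pi) / log(0.5)
  cov <- pi * h2 * (1 + r * h2)^d
  bins <- data.frame(k = seq_along(pi), lower = pi - 0.01, upper = pi + 0.01,
                     pi_mean = pi, n_pairs = 1000, cov = cov, se = 0)
  jack <- replicate(8, bins[, c("k", "pi_mean", "n_pairs", "cov")],
                    simplify = FALSE)
  bc <- structure(list(bins = bins, jack = jack, n_blocks = 8), class = "bin_cov")
  f <- fit_am(bc, min_pi = 0.05)
  expect_equal(f$h2_eq, h2, tolerance = 1e-10)
  expect_equal(f$r, r, tolerance = 1e-10)
  expect_equal(f$se_h2_eq, 0)
  expect_equal(exp(f$a), f$h2_eq)
  expect_equal((exp(f$b) - 1) / exp(f$a), f$r)
})

test_that("random-mating bins give zero slope and the origin-constrained HE slope", {
  h2 <- 0.5
  pi <- c(0.125, 0.25, 0.5)
  bins <- data.frame(k = 1:3, lower = 0, upper = 1, pi_mean = pi,
                     n_pairs = c(10, 20, 30), cov = h2 * pi, se = 0)
  jack <- replicate(5, bins[, c("k", "pi_mean", "n_pairs", "cov")],
                    simplify = FALSE)
  bc <- structure(list(bins = bins, jack = jack, n_blocks = 5), class = "bin_cov")
  f <- fit_am(bc)
  expect_equal(f$b, 0, tolerance = 1e-12)
  expect_equal(f$h2_eq, h2, tolerance = 1e-12)  # = slope through the origin
})

test_that("non-positive bins are dropped with a warning", {
  bins <- data.frame(k = 1:3, lower = 0, upper = 1,
                     pi_mean = c(0.125, 0.25, 0.5),
                     n_pairs = 10, cov = c(-0.01, 0.15, 0.3), se = 0)
  jack <- replicate(4, bins[, c("k", "pi_mean", "n_pairs", "cov")],
                    simplify = FALSE)
  bc <- structure(list(bins = bins, jack = jack, n_blocks = 4), class = "bin_cov")
  expect_warning(f <- fit_am(bc), "non-positive")
  expect_equal(nrow(f$bins), 2)
})

test_that("design expectations under assortative mating match the identity", {
  e <- expected_design_params(0.82, 0.24)
  expect_equal(round(e$h2, 2), 0.66)
  expect_equal(e$c2_genetic, 0.82 - e$h2)
  expect_equal(expected_design_params(0.5, 0)$h2, 0.5)
  expect_equal(expected_design_params(0.5, 0)$c2_genetic, 0)
  expect_equal(expected_design_params(0.42, 0.60)$h2, 0.31416)
})

test_that("equilibrium inversion is the algebraic inverse of the expectation", {
  expect_equal(equilibrium_from_design(0.5, 0)$h2_eq, 0.5)
  expect_equal(equilibrium_from_design(0.66, 0.24)$h2_eq, 0.8223,
               tolerance = 1e-4)
  for (h2 in c(0.2, 0.5, 0.8, 0.95)) for (r in c(0, 0.1, 0.24, 0.4)) {
    fwd <- expected_design_params(h2, r)$h2
    expect_equal(equilibrium_from_design(fwd, r)$h2_eq, h2, tolerance = 1e-8)
  }
  expect_error(equilibrium_from_design(0.9, 0.9), "no real")
  # delta-method se shrinks with the input ses
  s1 <- equilibrium_from_design(0.66, 0.24, se_h2 = 0.07, se_r = 0.04)$se
  s2 <- equilibrium_from_design(0.66, 0.24, se_h2 = 0.01, se_r = 0.01)$se
  expect_gt(s1, s2)
  expect_gt(s1, 0.07)  # inversion amplifies uncertainty
})

test_that("twin estimator doubles the MZ-DZ correlation gap", {
  expect_equal(twin_estimate(0.8, 0.4), 0.8)
  expect_equal(twin_estimate(0.55, 0.55), 0)
})

test_that("simulated twins under random mating recover h2 via 2(rMZ - rDZ)", {
  co <- small_cohort(n = 4000, h2 = 0.6, c2 = 0.1, gens = 2, sibs = 2,
                     twins = c(mz = 0.3, dz = 0.3), seed = 61)
  ids <- analysis_ids(co, generations = 2)
  y <- cohort_y(co, ids)
  ped <- co$pedigree
  sib <- co$sib_ibd
  tw <- ped$twin[match(sib$id1, ped$id)]
  xp <- y[as.character(sib$id1)] * y[as.character(sib$id2)]
  same_tw <- ped$twin[match(sib$id2, ped$id)] == tw & tw != ""
  r_mz <- mean(xp[same_tw & tw == "MZ"])
  r_dz <- mean(xp[same_tw & tw == "DZ"])
  expect_lt(abs(r_mz - 0.7), 0.08)
  expect_lt(abs(r_dz - 0.4), 0.08)
  expect_lt(abs(twin_estimate(r_mz, r_dz) - 0.6), 0.2)
})
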