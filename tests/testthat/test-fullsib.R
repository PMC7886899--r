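test_that("a zero-length chromosome gives the two-coin-flip IBD distribution", {
  ibd <- simulate_sib_ibd(4000, map = data.frame(chrom = 1, cM = 0), seed = 71)
  expect_true(all(ibd %in% c(0, 0.5, 1)))
  tab <- table(factor(ibd, levels = c(0, 0.5, 1))) / 4000
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.04)
})

test_that("genome-wide IBD has mean 0.50 and realistic segregation SD", {
  ibd <- simulate_sib_ibd(10000, seed = 72)
  expect_lt(abs(mean(ibd) - 0.50), 0.002)
  expect_gt(sd(ibd), 0.033)
  expect_lt(sd(ibd), 0.041)
})

test_that("longer chromosomes have smaller sharing variance", {
  v50 <- var(simulate_sib_ibd(6000, map = data.frame(chrom = 1, cM = 50),
                              seed = 73))
  v300 <- var(simulate_sib_ibd(6000, map = data.frame(chrom = 1, cM = 300),
                               seed = 74))
  expect_gt(v50, v300)
  expect_error(simulate_sib_ibd(10, map = data.frame()), "empty")
})

test_that("noiseless pair regression recovers the generating line exactly", {
  set.seed(75)
  ibd <- simulate_sib_ibd(500)
  f <- pair_regression(ibd, xp = 0.1 + 0.6 * ibd)
  expect_equal(f$sigma2_a, 0.6, tolerance = 1e-10)
  expect_equal(f$sigma2_c, 0.1, tolerance = 1e-10)
  f0 <- pair_regression(ibd, xp = rep(0, length(ibd)))
  expect_equal(f0$sigma2_a, 0)
  expect_equal(f0$sigma2_c, 0)
  expect_error(pair_regression(rep(0.5, 10), xp = rnorm(10)), "segregation")
})

test_that("pair regression recovers simulated variance components", {
  d <- sim_sib_pairs(20000, 0.6, 0.2, 0.2, seed = 76)
  f <- pair_regression(d$ibd, d$y1, d$y2)
  expect_lt(abs(f$h2_fs - 0.6), 2 * f$se_h2)
  expect_lt(abs(f$c2_fs - 0.2), 2 * f$se_c2)
})

test_that("REML recovers the generating components and matches pair regression", {
  d <- sim_sib_pairs(4000, 0.6, 0.2, 0.2, seed = 77)
  y <- setNames(c(d$y1, d$y2), c(d$id1, d$id2))
  fam <- c(d$family, d$family)
  fr <- fit_variance_components(y, fam, d[, c("id1", "id2", "ibd")])
  expect_lt(abs(fr$h2_fs - 0.6), 2.5 * fr$se_h2)
  expect_lt(abs(fr$c2_fs - 0.2), 2.5 * fr$se_c2)
  expect_equal(fr$total, var(y), tolerance = 0.05)
  fp <- pair_regression(d$ibd, d$y1, d$y2)
  expect_lt(abs(fr$h2_fs - fp$h2_fs), 2 * sqrt(fp$se_h2^2 + fr$se_h2^2))
})

test_that("REML handles larger sibships and flags singleton degeneracy", {
  set.seed(78)
  # families of 3 sibs built from the generative model
  nfam <- 400
  ylist <- list(); fam <- integer(0); ibd <- NULL
  for (f in seq_len(nfam)) {
    k12 <- simulate_sib_ibd(3)  # approximate within-trio IBDs
    A <- diag(3); A[1, 2] <- A[2, 1] <- k12[1]
    A[1, 3] <- A[3, 1] <- k12[2]; A[2, 3] <- A[3, 2] <- k12[3]
    V <- A * 0.5 + matrix(1, 3, 3) * 0.2 + diag(3) * 0.3
    yv <- drop(t(chol(V)) %*% rnorm(3))
    ids <- paste0("f", f, "_", 1:3)
    ylist[[f]] <- setNames(yv, ids)
    fam <- c(fam, rep(f, 3))
    ibd <- rbind(ibd, data.frame(id1 = ids[c(1, 1, 2)], id2 = ids[c(2, 3, 3)],
                                 ibd = k12))
  }
  y <- unlist(ylist)
  fr <- fit_variance_components(y, fam, ibd)
  expect_lt(abs(fr$h2_fs - 0.5), 3 * fr$se_h2)
  expect_equal(fr$n_pairs, 3 * nfam)

  expect_warning(f0 <- fit_variance_components(setNames(rnorm(50), 1:50), 1:50),
                 "singleton")
  expect_equal(f0$sigma2_a, 0)
})

test_that("h2_fs is unaffected by between-family environmental covariance", {
  d <- sim_sib_pairs(15000, 0.5, 0.0, 0.5, seed = 79)
  fam_env <- rnorm(nrow(d), 0, sqrt(0.3))
  f0 <- pair_regression(d$ibd, d$y1, d$y2)
  f1 <- pair_regression(d$ibd, d$y1 + fam_env, d$y2 + fam_env)
  # shared environment loads on the intercept, not the slope
  expect_lt(abs(f1$sigma2_a - f0$sigma2_a), 2 * sqrt(2) * f1$se_h2 * f1$total)
  expect_gt(f1$sigma2_c, f0$sigma2_c + 0.15)
})

test_that("full-sib correlation and its Fisher approximation evaluate correctly", {
  r <- fullsib_correlation(0.231, 0.597, 19954)
  expect_equal(round(r$r_fs, 2), 0.53)
  expect_equal(round(r$se, 2), 0.01)
  expect_equal(fullsib_correlation(0, 0.5, 100)$r_fs, 0.25)
  se_small <- fullsib_correlation(0.2, 0.4, 1000)$se
  se_big <- fullsib_correlation(0.2, 0.4, 10000)$se
  expect_gt(se_small, se_big)
  expect_error(fullsib_correlation(0.8, 0.6, 100), "outside")
})
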