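make_pheno_table <- function(n = 2000, seed = 41, batch_effect = 0,
                             n_pcs = 0) {
  set.seed(seed)
  tab <- data.frame(sex = sample(1:2, n, TRUE), batch = sample(1:6, n, TRUE),
                    age = sample(40:70, n, TRUE), yob = sample(1937:1970, n, TRUE))
  tab$y <- rnorm(n)
  if (batch_effect > 0) {
    be <- rnorm(6)
    shift <- be[tab$batch] - mean(be[tab$batch])
    tab$y <- tab$y + shift * sqrt(batch_effect * var(tab$y) / var(shift))
  }
  if (n_pcs > 0) for (j in seq_len(n_pcs)) tab[[paste0("pc", j)]] <- rnorm(n)
  tab
}

test_that("a phenotype equal to a covariate effect leaves zero residuals", {
  tab <- make_pheno_table(500)
  tab$y <- c(1.5, -2)[tab$sex] + 0.1 * (tab$batch)
  m <- fit_covariate_model(tab, 1)
  expect_lt(max(abs(m$residuals)), 1e-10)
})

test_that("orthogonal covariates leave the centred phenotype", {
  n <- 400
  tab <- data.frame(sex = rep(1:2, n / 2), batch = rep(1:2, each = n / 2),
                    age = 50, yob = 1950)
  set.seed(42)
  y <- rnorm(n)
  # orthogonalise y against the design so covariates explain nothing
  X <- model.matrix(~ factor(sex) + factor(batch), tab)
  y <- resid(lm(y ~ X))
  tab$y <- y
  m <- fit_covariate_model(tab, 1)
  expect_equal(m$residuals, y - mean(y), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("an injected batch share is removed by the model fit", {
  tab <- make_pheno_table(20000, batch_effect = 0.05)
  m <- fit_covariate_model(tab, 1)
  expect_equal(var(m$residuals) / var(tab$y), 0.95, tolerance = 0.01)
})

test_that("the outlier filter removes beyond-threshold points only", {
  set.seed(43)
  x <- as.numeric(scale(rnorm(100000)))
  x2 <- c(x, 4.9, 5.1)
  o <- exclude_outliers(x2, k_sd = 5)
  expect_false(o$keep[length(x2)])       # 5.1 SDs removed
  expect_true(o$keep[length(x2) - 1])    # 4.9 SDs kept
  expect_equal(o$n_removed, 1)

  o2 <- exclude_outliers(rnorm(100), k_sd = 5)
  expect_equal(o2$n_removed, 0)
  o3 <- exclude_outliers(rep(3, 10))
  expect_equal(o3$n_removed, 0)          # zero variance: nothing removed
})

test_that("the 5-SD removal fraction matches the normal tail probability", {
  set.seed(44)
  x <- rnorm(1e6)
  o <- exclude_outliers(x, k_sd = 5)
  # expected count 2 phi(-5) * 1e6 ~ 0.57; a handful at most
  expect_lte(o$n_removed, 5)
})

test_that("within-sex standardisation gives per-group mean 0 and variance 1", {
  x <- c(1, 3, 10, 30)
  sex <- c(1, 1, 2, 2)
  z <- standardize_within_sex(x, sex)
  for (s in 1:2) {
    expect_equal(mean(z[sex == s]), 0)
    expect_equal(var(z[sex == s]), 1)
  }
  # two-point groups land at +-1/sqrt(2) under the sample-variance convention
  expect_equal(z, c(-1, 1, -1, 1) / sqrt(2))
  expect_equal(standardize_within_sex(z, sex), z, tolerance = 1e-12)
  expect_error(standardize_within_sex(c(1, 2, 3), c(1, 1, 2)), "single")
})

test_that("pooled variance is ~1 when the sexes have equal means", {
  set.seed(45)
  x <- rnorm(4000)
  sex <- sample(1:2, 4000, TRUE)
  z <- standardize_within_sex(x, sex)
  expect_equal(var(z), 1, tolerance = 0.01)
})

test_that("phenotype prep is idempotent and model 4 nests model 1", {
  tab <- make_pheno_table(3000, batch_effect = 0.04, n_pcs = 3)
  tab$cg <- sample(1:15, nrow(tab), TRUE)
  p1 <- prep_phenotype(tab, model_id = 1)
  # re-running prep on its own output changes nothing
  tab2 <- tab
  tab2$y <- p1$y_prep
  p2 <- prep_phenotype(tab2, model_id = 1)
  expect_equal(p2$y_prep[p1$included], p1$y_prep[p1$included], tolerance = 1e-10)

  m1 <- fit_covariate_model(tab, 1)
  m4 <- fit_covariate_model(tab, 4)
  expect_lte(var(m4$residuals), var(m1$residuals) + 1e-12)
})

test_that("partial R2 recovers injected shares and is 0 for included factors", {
  tab <- make_pheno_table(3000)
  tab$cg <- sample(1:10, nrow(tab), TRUE)
  expect_equal(partial_r2(tab, "batch", 1), 0)
  expect_lt(partial_r2(tab, "cg", 1), 0.01)   # nothing injected

  co <- small_cohort(n = 6000, h2 = 0.4, gens = 1, seed = 46)
  co <- simulate_covariate_stratification(co, n_cg = 10, cg_share = 0.02)
  tab2 <- merge(co$covariates, co$pheno[, c("id", "y_raw")], by = "id")
  tab2$y <- tab2$y_raw
  expect_lt(abs(partial_r2(tab2, "cg", 1) - 0.02), 0.012)
})

test_that("stratification validates shares and supports 378 groups", {
  co <- small_cohort(n = 1000, gens = 1, seed = 47)
  expect_error(simulate_covariate_stratification(co, cg_share = 0.6,
                                                 batch_share = 0.5), "sum")
  co2 <- small_cohort(n = 4000, gens = 1, seed = 48)
  co2 <- simulate_covariate_stratification(co2, n_cg = 378, cg_share = 0.01)
  expect_equal(length(unique(co2$covariates$cg)), 378)
  expect_equal(ncol(co2$covariates) - 6, 10)  # pc1..pc10 added
})
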