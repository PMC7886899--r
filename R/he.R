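# Haseman-Elston regression across the relatedness spectrum.
#
# The slope of phenotype cross-products on genomic relationship estimates
# heritability: restricted to nominally unrelated pairs (pi < 0.02) it
# estimates the SNP-based heritability (variance tagged by the markers);
# restricted to close relatives (pi > 0.05) it approaches the pedigree
# heritability. All fits carry an intercept, which is itself informative
# (assortative mating and shared environment push it above zero).

#' Generic blocked jackknife standard error
#'
#' Individuals are randomly partitioned into `n_blocks` blocks; the
#' statistic is recomputed with each block deleted, and
#' `se = sqrt(((B-1)/B) * sum((theta_b - mean(theta_b))^2))`.
#'
#' @param statistic_fn Function taking a vector of retained individual ids.
#' @param individuals Vector of ids.
#' @param n_blocks Number of blocks (default 100).
#' @param seed Seed for the block assignment.
#' @return List with `se`, the replicate values `replicates`, and `blocks`.
#' @export
blocked_jackknife <- function(statistic_fn, individuals, n_blocks = 100L,
                              seed = 1L) {
  blk <- jackknife_blocks(length(individuals), n_blocks, seed = seed)
  reps <- vapply(seq_len(n_blocks), function(b) {
    v <- statistic_fn(individuals[blk != b])
    if (!is.finite(v)) stop("statistic undefined when deleting block ", b)
    v
  }, 0)
  list(se = jackknife_se(reps), replicates = reps, blocks = blk)
}

jackknife_se <- function(reps) {
  reps <- reps[is.finite(reps)]
  B <- length(reps)
  if (B < 2) return(NA_real_)
  sqrt((B - 1) / B * sum((reps - mean(reps))^2))
}

new_he_fit <- function(coefs, ses, method, range, nbins, extra = NULL) {
  structure(c(list(slope = unname(coefs["slope"]),
                   intercept = unname(coefs["intercept"]),
                   se_slope = unname(ses["slope"]),
                   se_intercept = unname(ses["intercept"]),
                   method = method, pi_range = range, n_used = nbins),
              extra),
            class = "he_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf("he_fit (%s), pi range [%g, %g): slope %.4f (se %.4f), intercept %.4g (se %.4g)\n",
              x$method, x$pi_range[1], x$pi_range[2], x$slope, x$se_slope,
              x$intercept, x$se_intercept))
  if (!is.null(x$quadratic))
    cat(sprintf("  quadratic %.4f (se %.4f), Wald z %.2f, p %.3g\n",
                x$quadratic, x$se_quadratic, x$z_quadratic, x$p_quadratic))
  invisible(x)
}

bins_in_range <- function(bins, pi_range) {
  ok <- is.finite(bins$pi_mean) & bins$n_pairs > 0 &
    bins$pi_mean >= pi_range[1] & bins$pi_mean < pi_range[2]
  bins[ok, , drop = FALSE]
}

wls_coef <- function(bins, quadratic = FALSE) {
  if (quadratic) {
    f <- stats::lm(cov ~ pi_mean + I(pi_mean^2), data = bins,
                   weights = bins$n_pairs)
    stats::coef(f)
  } else {
    f <- stats::lm(cov ~ pi_mean, data = bins, weights = bins$n_pairs)
    stats::coef(f)
  }
}

#' Weighted-bin Haseman-Elston regression
#'
#' Weighted least squares of per-bin mean cross-product on per-bin mean
#' relationship, weights equal to the pair count per bin. With the default
#' unrelated range (`pi < 0.02`) the slope estimates the SNP-based
#' heritability; with the close-relative range (`pi > 0.05`) it estimates
#' the heritability from close relatives. Standard errors come from the
#' blocked-jackknife replicates carried by the `bin_cov` object.
#'
#' @param bincov A `bin_cov` object ([bin_covariance()] /
#'   [relatedness_bins()]).
#' @param pi_range Two values; bins with `pi_range[1] <= pi_mean <
#'   pi_range[2]` are used.
#' @return An `he_fit` with slope, intercept and jackknife ses.
#' @export
weighted_he <- function(bincov, pi_range = c(-Inf, 0.02)) {
  use <- bins_in_range(bincov$bins, pi_range)
  if (nrow(use) < 2) stop("need at least 2 non-empty bins in the pi range")
  cf <- wls_coef(use)
  reps <- vapply(bincov$jack, function(j) {
    u <- bins_in_range(j, pi_range)
    if (nrow(u) < 2) return(c(NA_real_, NA_real_))
    wls_coef(u)
  }, numeric(2))
  new_he_fit(c(intercept = cf[[1]], slope = cf[[2]]),
             c(intercept = jackknife_se(reps[1, ]),
               slope = jackknife_se(reps[2, ])),
             "weighted-bin", pi_range, nrow(use))
}

#' Individual-pair Haseman-Elston regression
#'
#' Ordinary least squares of the phenotype cross-product on the genomic
#' relationship over pairs in the given range, with blocked-jackknife ses
#' (pairs are deleted when either member's block is deleted).
#'
#' @param pairs Pair table with columns `id_i`, `id_j`, `pi` (excluded pairs
#'   dropped).
#' @param y Named phenotype vector.
#' @param pi_range Relationship range (half-open).
#' @param n_blocks,seed Jackknife configuration.
#' @return An `he_fit`.
#' @export
individual_he <- function(pairs, y, pi_range = c(-Inf, 0.02),
                          n_blocks = 100L, seed = 1L) {
  p <- pairs[!pairs$excluded & pairs$pi >= pi_range[1] & pairs$pi < pi_range[2], ]
  if (nrow(p) < 2) stop("need at least 2 pairs in the pi range")
  if (stats::var(p$pi) == 0) stop("no relationship variance among pairs in range")
  xp <- unname(y[as.character(p$id_i)] * y[as.character(p$id_j)])
  ids <- sort(unique(c(p$id_i, p$id_j)))
  nb <- min(n_blocks, length(ids))
  blk <- stats::setNames(jackknife_blocks(length(ids), nb, seed = seed), ids)
  # sufficient statistics per jackknife block pair; replicates by subtraction
  bp <- block_pair_index(blk[as.character(p$id_i)], blk[as.character(p$id_j)], nb)
  S <- rowsum(unname(cbind(1, p$pi, xp, p$pi * xp, p$pi^2)), bp)
  cells <- as.integer(rownames(S))
  ols <- function(s) {
    n <- s[1]
    vx <- s[5] - s[2]^2 / n
    if (n < 2 || vx <= 0) return(c(NA_real_, NA_real_))
    b <- (s[4] - s[2] * s[3] / n) / vx
    unname(c(s[3] / n - b * s[2] / n, b))
  }
  full <- colSums(S)
  cf <- ols(full)
  lab <- block_pair_labels(nb)[cells, , drop = FALSE]
  reps <- vapply(seq_len(nb), function(b) {
    touch <- lab[, 1] == b | lab[, 2] == b
    ols(full - colSums(S[touch, , drop = FALSE]))
  }, numeric(2))
  new_he_fit(c(intercept = cf[1], slope = cf[2]),
             c(intercept = jackknife_se(reps[1, ]),
               slope = jackknife_se(reps[2, ])),
             "individual", pi_range, nrow(p))
}

#' Two-component close-relative Haseman-Elston regression
#'
#' Mirrors the two-matrix mixed-model decomposition used on real data: over
#' pairs among individuals having at least one close relative, cross-products
#' are regressed on (i) the relationship zeroed below the threshold and
#' (ii) an indicator of being a close pair. Coefficient (i) estimates the
#' close-relative heritability; coefficient (ii) is the constant covariance
#' component shared by all flagged pairs (the intercept analogue).
#'
#' @param pairs Pair table.
#' @param y Named phenotype vector.
#' @param threshold Close-relative threshold (default 0.05).
#' @param n_blocks,seed Jackknife configuration.
#' @return An `he_fit`; `slope` is the close-relative heritability,
#'   `intercept` the constant component.
#' @export
two_component_he <- function(pairs, y, threshold = 0.05,
                             n_blocks = 100L, seed = 1L) {
  p <- pairs[!pairs$excluded, ]
  flag <- p$pi >= threshold
  if (!any(flag)) stop("no pairs at or above the close-relative threshold")
  close_ids <- unique(c(p$id_i[flag], p$id_j[flag]))
  keep <- p$id_i %in% close_ids & p$id_j %in% close_ids
  p <- p[keep, ]; flag <- flag[keep]
  xp <- unname(y[as.character(p$id_i)] * y[as.character(p$id_j)])
  u <- p$pi * flag; v <- as.numeric(flag)
  ids <- sort(unique(c(p$id_i, p$id_j)))
  nb <- min(n_blocks, length(ids))
  blk <- stats::setNames(jackknife_blocks(length(ids), nb, seed = seed), ids)
  bp <- block_pair_index(blk[as.character(p$id_i)], blk[as.character(p$id_j)], nb)
  # no-intercept two-regressor normal equations from block-pair sums
  S <- rowsum(unname(cbind(u^2, u * v, v^2, u * xp, v * xp)), bp)
  cells <- as.integer(rownames(S))
  solve2 <- function(s) {
    det <- s[1] * s[3] - s[2]^2
    if (!is.finite(det) || det <= 0) return(c(NA_real_, NA_real_))
    unname(c(s[3] * s[4] - s[2] * s[5], s[1] * s[5] - s[2] * s[4]) / det)
  }
  full <- colSums(S)
  cf <- solve2(full)   # (slope on pi*flag, flag coefficient)
  lab <- block_pair_labels(nb)[cells, , drop = FALSE]
  reps <- vapply(seq_len(nb), function(b) {
    touch <- lab[, 1] == b | lab[, 2] == b
    solve2(full - colSums(S[touch, , drop = FALSE]))
  }, numeric(2))
  new_he_fit(c(intercept = cf[2], slope = cf[1]),
             c(intercept = jackknife_se(reps[2, ]),
               slope = jackknife_se(reps[1, ])),
             "two-component", c(threshold, Inf), sum(flag))
}

#' Quadratic (additive-by-additive) bin regression
#'
#' Additive-by-additive epistatic variance contributes covariance
#' proportional to the squared relationship, so a quadratic term in the bin
#' regression estimates it. Reports the quadratic coefficient with a
#' blocked-jackknife Wald test.
#'
#' @param bincov A `bin_cov`.
#' @param pi_range Bins used (default: all).
#' @return An `he_fit` with `quadratic`, `se_quadratic`, `z_quadratic`,
#'   `p_quadratic` fields.
#' @export
epistasis_fit <- function(bincov, pi_range = c(-Inf, Inf)) {
  use <- bins_in_range(bincov$bins, pi_range)
  if (nrow(use) < 3) stop("need at least 3 non-empty bins for the quadratic fit")
  if (stats::var(use$pi_mean) == 0 || stats::var(use$pi_mean^2) == 0 ||
      abs(stats::cor(use$pi_mean, use$pi_mean^2)) > 1 - 1e-10)
    stop("pi and pi^2 are collinear over the selected bins")
  cf <- wls_coef(use, quadratic = TRUE)
  reps <- vapply(bincov$jack, function(j) {
    u <- bins_in_range(j, pi_range)
    if (nrow(u) < 3) return(rep(NA_real_, 3))
    wls_coef(u, quadratic = TRUE)
  }, numeric(3))
  ses <- unname(apply(reps, 1, jackknife_se))
  z <- cf[[3]] / ses[3]
  new_he_fit(c(intercept = cf[[1]], slope = cf[[2]]),
             c(intercept = ses[1], slope = ses[2]),
             "weighted-bin-quadratic", pi_range, nrow(use),
             extra = list(quadratic = cf[[3]], se_quadratic = ses[3],
                          z_quadratic = z,
                          p_quadratic = 2 * stats::pnorm(-abs(z))))
}
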