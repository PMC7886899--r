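# Equilibrium model of phenotypic assortative mating.
#
# Under positive assortment the additive genetic variance grows until a
# steady state; for a relative pair separated by d meioses the phenotypic
# covariance is approximately (0.5)^d h2_EQ (1 + r h2_EQ)^d, with r the
# correlation between mates and h2_EQ the equilibrium heritability.
# Replacing (0.5)^d by the binned genomic relationship pi_k gives a linear
# model in d_k = log(pi_k)/log(0.5): log(c_k / pi_k) = alpha + beta d_k with
# alpha = log(h2_EQ), beta = log(1 + r h2_EQ) -- invertible as
# h2_EQ = e^a, r = (e^b - 1)/e^a.

#' Expected covariance of a relative pair under assortative mating
#'
#' @param d Number of meioses separating the pair (non-integer allowed when
#'   derived from genomic relationships).
#' @param r Phenotypic correlation between mates.
#' @param h2_eq Equilibrium heritability.
#' @return `(0.5)^d * h2_eq * (1 + r * h2_eq)^d`.
#' @export
am_expected_cov <- function(d, r, h2_eq) {
  stopifnot(all(d >= 0), h2_eq >= 0, h2_eq <= 1, abs(r) <= 1)
  0.5^d * h2_eq * (1 + r * h2_eq)^d
}

#' Fit the assortative-mating model to close-relative bins
#'
#' Log-linear weighted regression of `log(c_k / pi_k)` on
#' `d_k = log(pi_k)/log(0.5)` over bins with mean relationship above
#' `min_pi`, back-transformed to the equilibrium heritability and the
#' correlation between mates. Standard errors are blocked-jackknife, from
#' the replicates carried by the `bin_cov`.
#'
#' @param bincov A `bin_cov` object.
#' @param min_pi Only bins with `pi_mean > min_pi` are used (default 0.05,
#'   the close-relative threshold).
#' @param weighted Weight bins by pair count (default TRUE; switchable
#'   because the weighting of this fit is a free choice).
#' @return An object of class `am_fit`: `a`, `b`, `h2_eq`, `r`, their ses,
#'   and the bin table used (with `d` and `y = c/pi`).
#' @export
fit_am <- function(bincov, min_pi = 0.05, weighted = TRUE) {
  fit1 <- function(bins) {
    use <- bins[is.finite(bins$pi_mean) & bins$n_pairs > 0 &
                  bins$pi_mean > min_pi & is.finite(bins$cov), , drop = FALSE]
    pos <- use$cov > 0
    use <- use[pos, , drop = FALSE]
    if (nrow(use) < 2) return(NULL)
    d <- log(use$pi_mean) / log(0.5)
    ly <- log(use$cov / use$pi_mean)
    w <- if (weighted) use$n_pairs else rep(1, nrow(use))
    cf <- stats::coef(stats::lm(ly ~ d, weights = w))
    list(a = cf[[1]], b = cf[[2]], bins = cbind(use, d = d, y = exp(ly)))
  }
  use0 <- bincov$bins[is.finite(bincov$bins$cov) & bincov$bins$n_pairs > 0 &
                        bincov$bins$pi_mean > min_pi, , drop = FALSE]
  if (any(use0$cov <= 0))
    warning(sum(use0$cov <= 0), " bin(s) with non-positive covariance dropped")
  full <- fit1(bincov$bins)
  if (is.null(full)) stop("fewer than 2 usable bins above min_pi")
  reps <- vapply(bincov$jack, function(j) {
    f <- fit1(j)
    if (is.null(f)) return(rep(NA_real_, 4))
    c(f$a, f$b, exp(f$a), (exp(f$b) - 1) / exp(f$a))
  }, numeric(4))
  ses <- apply(reps, 1, jackknife_se)
  structure(list(a = full$a, b = full$b,
                 h2_eq = exp(full$a), r = (exp(full$b) - 1) / exp(full$a),
                 se_a = ses[1], se_b = ses[2], se_h2_eq = ses[3], se_r = ses[4],
                 bins = full$bins, weighted = weighted, min_pi = min_pi),
            class = "am_fit")
}

#' @export
print.am_fit <- function(x, ...) {
  cat(sprintf("am_fit over %d bins (pi > %g): h2_eq = %.3f (se %.3f), r = %.3f (se %.3f)\n",
              nrow(x$bins), x$min_pi, x$h2_eq, x$se_h2_eq, x$r, x$se_r))
  invisible(x)
}

#' Design expectations under assortative mating
#'
#' Full-sib IBD regression and classic twin designs estimate within-family
#' genetic variance scaled by the current phenotypic variance; under
#' equilibrium assortative mating their expectation is
#' `h2_EQ (1 - r h2_EQ)`, not `h2_EQ` itself, and the displaced variance
#' `h2_EQ - h2_design` loads on the shared-environment estimate.
#'
#' @param h2_eq Equilibrium heritability.
#' @param r Correlation between mates.
#' @param design "fullsib", "twin" or "rdr-published" (all share the same
#'   expectation; recorded for provenance).
#' @return List with `h2` (expected design heritability), `c2_genetic` (the
#'   assortment-generated part of the apparent shared environment), and
#'   `design`.
#' @export
expected_design_params <- function(h2_eq, r, design = c("fullsib", "twin",
                                                        "rdr-published")) {
  design <- match.arg(design)
  stopifnot(h2_eq >= 0, h2_eq <= 1, abs(r) <= 1)
  h2 <- h2_eq * (1 - r * h2_eq)
  list(h2 = h2, c2_genetic = h2_eq - h2, design = design)
}

#' Invert a design estimate to the equilibrium heritability
#'
#' Solves `h2_design = x (1 - r x)` for `x = h2_EQ`, taking the smaller
#' quadratic root (the branch continuous with the random-mating limit
#' r -> 0). Standard errors propagate by the delta method when ses for the
#' design estimate and the spousal correlation are supplied.
#'
#' @param h2_design Design-based heritability estimate.
#' @param r Correlation between mates (>= 0).
#' @param se_h2,se_r Optional standard errors for delta-method propagation.
#' @return List with `h2_eq` and (when ses given) `se`.
#' @export
equilibrium_from_design <- function(h2_design, r, se_h2 = NULL, se_r = NULL) {
  stopifnot(r >= 0)
  solve1 <- function(h, r) {
    if (r == 0) return(h)
    disc <- 1 - 4 * r * h
    if (disc < 0) stop("inconsistent (h2, r) pair: no real equilibrium root")
    x <- (1 - sqrt(disc)) / (2 * r)
    if (x < 0 || x > 1) stop("equilibrium root outside [0, 1]")
    x
  }
  h2_eq <- solve1(h2_design, r)
  out <- list(h2_eq = h2_eq)
  if (!is.null(se_h2)) {
    eps <- 1e-6
    gh <- (solve1(h2_design + eps, r) - solve1(h2_design - eps, r)) / (2 * eps)
    gr <- if (r > eps) (solve1(h2_design, r + eps) - solve1(h2_design, r - eps)) / (2 * eps)
          else (solve1(h2_design, r + eps) - solve1(h2_design, r)) / eps
    if (is.null(se_r)) se_r <- 0
    out$se <- sqrt(gh^2 * se_h2^2 + gr^2 * se_r^2)
  }
  out
}

#' Classic twin heritability estimate
#'
#' @param r_mz,r_dz Phenotypic correlations of monozygotic and dizygotic
#'   twin pairs.
#' @return `2 * (r_mz - r_dz)`.
#' @export
twin_estimate <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  2 * (r_mz - r_dz)
}
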