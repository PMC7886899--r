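# Fixed-effect inverse-variance meta-analysis of full-sib regression
# results and derived correlations.

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; combined estimate `sum(w x)/sum(w)` with
#' `se = 1/sqrt(sum(w))`. Cochran's Q is reported for information (no
#' random-effects model is fitted).
#'
#' @param estimate Per-study estimates.
#' @param se Per-study standard errors (> 0).
#' @param labels Optional study labels.
#' @return Object of class `meta_result`: `estimate`, `se`, normalised
#'   `weights`, `q` and `n_studies`.
#' @export
ivw_meta <- function(estimate, se, labels = NULL) {
  stopifnot(length(estimate) == length(se), length(estimate) >= 1)
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  est <- sum(w * estimate) / sum(w)
  structure(list(estimate = est, se = 1 / sqrt(sum(w)),
                 weights = stats::setNames(w / sum(w), labels),
                 q = sum(w * (estimate - est)^2),
                 n_studies = length(estimate)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: %d studies, estimate %.4f (se %.4f), Q = %.2f\n",
              x$n_studies, x$estimate, x$se, x$q))
  invisible(x)
}

#' Meta-analysis of full-sib correlations derived from regression components
#'
#' Per study, `r_FS = c2 + h2/2` with `se = sqrt((1 - r_FS^2)/N)`, then
#' inverse-variance combination.
#'
#' @param studies Data.frame with columns `c2`, `h2`, `n_pair` (and
#'   optionally `study` labels).
#' @return A `meta_result`; the per-study correlations are attached as
#'   attribute "per_study".
#' @export
meta_fullsib_correlation <- function(studies) {
  stopifnot(all(c("c2", "h2", "n_pair") %in% names(studies)))
  per <- mapply(function(c2, h2, n) unlist(fullsib_correlation(c2, h2, n)),
                studies$c2, studies$h2, studies$n_pair)
  out <- ivw_meta(per["r_fs", ], per["se", ], labels = studies$study)
  attr(out, "per_study") <- data.frame(study = studies$study %||% seq_len(ncol(per)),
                                       r_fs = per["r_fs", ], se = per["se", ])
  out
}

#' Published full-sib IBD regression studies
#'
#' The packaged per-study estimates (three cohorts for height and BMI, two
#' for educational attainment): sib-pair counts and full-sib regression
#' shared-environment and heritability components with standard errors, as
#' printed in the source publications.
#'
#' @return Data.frame: trait, study, n_pair, c2, c2_se, h2, h2_se.
#' @export
fullsib_studies <- function() {
  path <- system.file("extdata", "fullsib_studies.tsv", package = "relspectrum",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
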