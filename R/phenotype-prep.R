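# Phenotype pre-adjustment: fixed-effect models, outlier filtering, and
# within-sex standardisation. The residual standardised phenotype is the
# quantity every downstream pair analysis works with.

model_terms <- function(model_id) {
  base <- c("sex", "batch", "age", "yob")
  switch(as.character(model_id),
         "1" = base,
         "2" = c(base, "cg"),
         "3" = c(base, "PCS"),
         "4" = c(base, "PCS", "cg"),
         stop("model_id must be 1, 2, 3 or 4"))
}

build_formula <- function(table, model_id, response = "y") {
  terms <- model_terms(model_id)
  pcs <- grep("^pc[0-9]+$", names(table), value = TRUE)
  if ("PCS" %in% terms) {
    if (!length(pcs)) stop("model ", model_id, " needs PC score columns (pc1, pc2, ...)")
    terms <- c(setdiff(terms, "PCS"), pcs)
  }
  fac <- intersect(terms, c("sex", "batch", "age", "yob", "cg"))
  # constant factors carry no contrast; drop them with a note
  const <- fac[vapply(fac, function(f) length(unique(table[[f]])) < 2, TRUE)]
  if (length(const)) {
    message("constant covariate(s) dropped from model: ",
            paste(const, collapse = ", "))
    fac <- setdiff(fac, const)
  }
  num <- setdiff(terms, c(fac, const))
  rhs <- c(paste0("factor(", fac, ")"), num)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a fixed-effect covariate model and return residuals
#'
#' Ordinary least squares of the raw trait on the covariates of the chosen
#' model: (1) sex + batch + age + yob, (2) adds contemporary group,
#' (3) adds PC scores, (4) adds both. Categorical covariates (including age
#' and year of birth) enter as factors. Aliased columns from rank
#' deficiency are dropped with a message; single-observation factor levels
#' are retained with a warning.
#'
#' @param table Data.frame with a `y` column and the model's covariates
#'   (`sex`, `batch`, `age`, `yob`, optionally `cg` and `pc1...`).
#' @param model_id 1, 2, 3 or 4.
#' @return List: `residuals` (NA where y missing), `fit`, `r_squared`, and
#'   `term_r2` (variance explained per term, sequential).
#' @export
fit_covariate_model <- function(table, model_id = 1L) {
  fml <- build_formula(table, model_id)
  fac <- intersect(model_terms(model_id), c("sex", "batch", "age", "yob", "cg"))
  for (f in fac) {
    tabf <- base::table(table[[f]])
    if (any(tabf == 1))
      warning("factor ", f, " has ", sum(tabf == 1), " level(s) with one observation")
  }
  fit <- stats::lm(fml, data = table, na.action = stats::na.exclude)
  if (any(is.na(stats::coef(fit))))
    message(sum(is.na(stats::coef(fit))), " aliased coefficient(s) dropped")
  an <- stats::anova(fit)
  tss <- sum(an[, "Sum Sq"])
  term_r2 <- stats::setNames(an[-nrow(an), "Sum Sq"] / tss,
                             rownames(an)[-nrow(an)])
  list(residuals = stats::resid(fit), fit = fit,
       r_squared = suppressWarnings(summary(fit))$r.squared, term_r2 = term_r2)
}

#' Exclude extreme observations
#'
#' Single-pass removal of values more than `k_sd` sample standard
#' deviations from the mean (default 5).
#'
#' @param x Numeric vector (NAs passed through as excluded).
#' @param k_sd Threshold in SD units.
#' @return List: `values` (retained), `keep` (logical on the input),
#'   `n_removed`.
#' @export
exclude_outliers <- function(x, k_sd = 5) {
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  s <- stats::sd(x[ok])
  keep <- ok
  if (s > 0) keep <- ok & abs(x - mean(x[ok])) <= k_sd * s
  list(values = x[keep], keep = keep, n_removed = sum(ok) - sum(keep))
}

#' Standardise residuals within sex
#'
#' Centres and scales to unit sample variance within each sex group; this
#' residual standardised value is the working definition of phenotype for
#' all pair analyses.
#'
#' @param x Numeric vector.
#' @param sex Group labels (2 expected).
#' @return Numeric vector, per-group mean 0 and sample variance 1.
#' @export
standardize_within_sex <- function(x, sex) {
  stopifnot(length(x) == length(sex))
  out <- rep(NA_real_, length(x))
  for (s in unique(sex[!is.na(sex)])) {
    ix <- which(sex == s & is.finite(x))
    if (length(ix) == 1) stop("sex group '", s, "' has a single observation")
    if (length(ix) == 0) next
    out[ix] <- (x[ix] - mean(x[ix])) / stats::sd(x[ix])
  }
  out
}

#' Full phenotype preparation pipeline
#'
#' Fits the covariate model, removes observations more than `k_sd` SDs from
#' the mean of the residuals (one pass), then alternates refitting and
#' within-sex standardisation until the prepared values are a fixed point
#' of the adjustment, so running prep on its own output changes nothing.
#' (The outlier pass can alternatively be applied to the raw values before
#' any fit.)
#'
#' @param table Data.frame with `y` and covariates (see
#'   [fit_covariate_model()]).
#' @param model_id Covariate model 1-4.
#' @param k_sd Outlier threshold in SDs.
#' @param outlier_on "residuals" (default) or "raw".
#' @return The table with columns `y_prep` (NA for excluded rows),
#'   `included`, `exclusion_reason`; attributes record counts.
#' @export
prep_phenotype <- function(table, model_id = 1L, k_sd = 5,
                           outlier_on = c("residuals", "raw")) {
  outlier_on <- match.arg(outlier_on)
  tab <- table
  reason <- rep("", nrow(tab))
  reason[!is.finite(tab$y)] <- "missing"
  if (outlier_on == "raw") {
    o <- exclude_outliers(tab$y, k_sd)
    reason[!o$keep & reason == ""] <- "outlier"
    tab$y[!o$keep] <- NA
  }
  m1 <- fit_covariate_model(tab, model_id)
  if (outlier_on == "residuals") {
    o <- exclude_outliers(m1$residuals, k_sd)
    reason[!o$keep & is.finite(tab$y)] <- "outlier"
    tab$y[!o$keep] <- NA
    m1 <- fit_covariate_model(tab, model_id)
  }
  yp <- standardize_within_sex(m1$residuals, tab$sex)
  # within-sex rescaling can reintroduce tiny covariate components when the
  # two sex groups get different scale factors; iterate to the fixed point
  for (it in 1:25) {
    tab$y <- yp
    m1 <- fit_covariate_model(tab, model_id)
    yp_new <- standardize_within_sex(m1$residuals, tab$sex)
    delta <- max(abs(yp_new - yp), na.rm = TRUE)
    yp <- yp_new
    if (is.finite(delta) && delta < 1e-11) break
  }
  out <- table
  out$y_prep <- yp
  out$included <- is.finite(yp)
  out$exclusion_reason <- reason
  attr(out, "n_removed") <- sum(reason == "outlier")
  attr(out, "model_id") <- model_id
  out
}

#' Partial R-squared of a factor given a baseline model
#'
#' `(RSS_baseline - RSS_full) / TSS` where the full model adds `factor` to
#' the baseline; both are fitted on the rows complete for the full model.
#'
#' @param table Data with `y` and covariates.
#' @param factor Name of the column whose additional contribution is wanted
#'   (fitted as a factor).
#' @param baseline_model Baseline model id (1-4) or a formula.
#' @return The partial R-squared (share of total variance).
#' @export
partial_r2 <- function(table, factor, baseline_model = 1L) {
  fml0 <- if (inherits(baseline_model, "formula")) baseline_model
          else build_formula(table, baseline_model)
  vars0 <- all.vars(fml0)
  if (factor %in% vars0) return(0)
  fml1 <- stats::update(fml0, stats::as.formula(paste(". ~ . + factor(", factor, ")")))
  rows <- stats::complete.cases(table[, unique(c(all.vars(fml1))), drop = FALSE])
  d <- table[rows, , drop = FALSE]
  f0 <- stats::lm(fml0, data = d)
  f1 <- stats::lm(fml1, data = d)
  if (!all(labels(stats::terms(f0)) %in% labels(stats::terms(f1))))
    stop("baseline model is not nested in the full model")
  tss <- sum((d$y - mean(d$y))^2)
  (sum(stats::resid(f0)^2) - sum(stats::resid(f1)^2)) / tss
}
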