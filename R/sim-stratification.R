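#' Inject covariate stratification into a cohort
#'
#' Adds geographic, technical and genetic stratification on top of a
#' simulated cohort: birth contemporary-group (CG) labels with CG-level
#' phenotype shifts, genotyping-batch effects, and principal-component
#' scores correlated with a heritable ancestry gradient. The gradient is
#' drawn for founders and transmitted as the parental midpoint plus noise,
#' so it is familial (as real ancestry is); CG membership follows the
#' gradient plus noise. Optionally a set of ancestry-informative markers has
#' its allele frequencies shifted along the gradient (applied as family-level
#' haplotype perturbations so MZ co-twins stay genotypically identical).
#'
#' Injected variance shares are expressed relative to the pre-stratification
#' phenotypic variance and recorded in `cohort$log$strat` for later recovery
#' checks.
#'
#' @param cohort A `cohort`.
#' @param n_cg Number of contemporary groups (the study design this mirrors
#'   used 378 local-authority groups).
#' @param cg_share,batch_share,pc_share Variance shares injected through CG,
#'   batch and the ancestry gradient (the latter is what PCs should absorb).
#' @param n_pcs Number of PC scores to attach.
#' @param n_aims Number of marker variants given gradient-dependent allele
#'   frequencies (0 disables genotype perturbation).
#' @return The cohort with `cg`, `pc1..pcK` columns added to `covariates`,
#'   phenotypes shifted, and the injected shares logged.
#' @export
simulate_covariate_stratification <- function(cohort, n_cg = 20L,
                                              cg_share = 0, batch_share = 0,
                                              pc_share = 0, n_pcs = 10L,
                                              n_aims = 0L) {
  if (cg_share + batch_share + pc_share > 1)
    stop("injected variance shares sum to more than 1")
  ped <- cohort$pedigree
  n <- nrow(ped)

  # heritable ancestry gradient: founder draw, then midparent + noise
  u <- numeric(n)
  fa_row <- match(ped$father, ped$id)
  mo_row <- match(ped$mother, ped$id)
  noise <- rnorm(n)
  for (g in sort(unique(ped$generation))) {
    i <- which(ped$generation == g)
    root <- is.na(fa_row[i])
    u[i[root]] <- noise[i[root]]
    nr <- i[!root]
    u[nr] <- (u[fa_row[nr]] + u[mo_row[nr]]) / 2 + 0.3 * noise[nr]
  }
  u <- as.numeric(scale(u))

  cg <- as.integer(cut(u + rnorm(n, 0, 0.5), breaks = stats::quantile(
    u + rnorm(n, 0, 0.001), probs = seq(0, 1, length.out = n_cg + 1)),
    include.lowest = TRUE, labels = FALSE))
  cg[is.na(cg)] <- sample.int(n_cg, sum(is.na(cg)), replace = TRUE)

  prow <- match(ped$id, cohort$pheno$id)
  y <- cohort$pheno$y_raw[prow]
  v0 <- stats::var(y, na.rm = TRUE)
  add_effect <- function(vec, share) {
    if (share <= 0 || stats::var(vec) == 0) return(0)
    vec <- vec - mean(vec)
    vec * sqrt(share * v0 / stats::var(vec))
  }
  cg_eff <- add_effect(rnorm(n_cg)[cg], cg_share)
  batch <- cohort$covariates$batch[match(ped$id, cohort$covariates$id)]
  batch_eff <- add_effect(rnorm(max(batch))[batch], batch_share)
  pc_eff <- add_effect(u, pc_share)
  cohort$pheno$y_raw[prow] <- y + cg_eff + batch_eff + pc_eff

  pcs <- sapply(seq_len(n_pcs), function(j) {
    w <- 0.9^j
    as.numeric(scale(w * u + sqrt(max(0, 1 - w^2)) * rnorm(n)))
  })
  colnames(pcs) <- paste0("pc", seq_len(n_pcs))
  crow <- match(ped$id, cohort$covariates$id)
  cohort$covariates$cg <- NA_integer_
  cohort$covariates$cg[crow] <- cg
  for (j in seq_len(n_pcs)) cohort$covariates[[paste0("pc", j)]] <- pcs[crow, j]

  if (n_aims > 0) {
    mk <- which(cohort$variant_role == "marker" & is.na(cohort$tag_of))
    aims <- sample(mk, min(n_aims, length(mk)))
    fam_u <- tapply(u[match(cohort$geno_ids, ped$id)],
                    ped$family[match(cohort$geno_ids, ped$id)], mean)
    fams <- ped$family[match(cohort$geno_ids, ped$id)]
    shift <- stats::plogis(fam_u[match(fams, as.integer(names(fam_u)))]) - 0.5
    for (l in aims) {
      flip <- runif(length(unique(fams))) < abs(shift[!duplicated(fams)])
      flip_ind <- flip[match(fams, unique(fams))]
      up <- flip_ind & shift > 0
      dn <- flip_ind & shift < 0
      cohort$hapA[up, l] <- 1L
      cohort$hapA[dn, l] <- 0L
    }
    cohort$log$strat_aims <- aims
  }

  cohort$log$strat <- list(cg_share = cg_share, batch_share = batch_share,
                           pc_share = pc_share, n_cg = n_cg)
  cohort
}
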