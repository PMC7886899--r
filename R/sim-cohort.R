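# Multi-generation cohort simulator: phenotypic assortative mating, Mendelian
# transmission with crossovers, family structure, shared environment and
# additive-by-additive epistasis.

# Draw effect sizes and centring constants once, on the founder genotypes.
# Additive values are beta' (x - xbar0); epistatic values are sums of
# gamma * z_a z_b over disjoint causal pairs (z = founder-centred dosage).
# Both are rescaled so their founder variances equal h2_rm and v_aa exactly.
genetic_effects <- function(geno, config) {
  nc <- config$n_causal
  x <- geno$hapA[, seq_len(nc), drop = FALSE] + geno$hapB[, seq_len(nc), drop = FALSE]
  center <- colMeans(x)
  z <- sweep(x, 2, center)
  eff <- list(center = center, n_causal = nc)
  if (config$h2_rm > 0) {
    beta <- rnorm(nc)
    a <- drop(z %*% beta)
    beta <- beta * sqrt(config$h2_rm / stats::var(a))
  } else beta <- rep(0, nc)
  eff$beta <- beta
  npair <- nc %/% 2
  eff$aa_pairs <- cbind(seq_len(npair), npair + seq_len(npair))
  if (config$v_aa > 0) {
    gamma <- rnorm(npair)
    e <- drop((z[, eff$aa_pairs[, 1]] * z[, eff$aa_pairs[, 2]]) %*% gamma)
    gamma <- gamma * sqrt(config$v_aa / stats::var(e))
  } else gamma <- rep(0, npair)
  eff$gamma <- gamma
  eff
}

# Additive and epistatic genetic values for a haplotype batch.
genetic_values <- function(hapA, hapB, effects) {
  nc <- effects$n_causal
  z <- sweep(hapA[, seq_len(nc), drop = FALSE] + hapB[, seq_len(nc), drop = FALSE],
             2, effects$center)
  a <- drop(z %*% effects$beta)
  aa <- if (any(effects$gamma != 0)) {
    drop((z[, effects$aa_pairs[, 1]] * z[, effects$aa_pairs[, 2]]) %*% effects$gamma)
  } else rep(0, nrow(hapA))
  list(a = a, aa = aa)
}

# Pair mates so the realised phenotypic correlation approximates target_r:
# both sexes are ranked on phenotype plus noise whose scale is calibrated by
# bisection; ranks are then matched. Within-family couples are repaired by
# local swaps (mating between sibs is excluded, as the equilibrium theory
# assumes). Deterministic given the RNG state.
match_mates <- function(y, sex, target_r, family = NULL) {
  males <- which(sex == 1L)
  females <- which(sex == 2L)
  ncpl <- min(length(males), length(females))
  males <- males[seq_len(ncpl)]
  females <- females[seq_len(ncpl)]
  fix_incest <- function(f, m) {
    if (is.null(family)) return(list(f = f, m = m))
    for (pass in 1:3) {
      bad <- which(family[f] == family[m])
      if (!length(bad)) break
      for (i in bad) {
        if (family[f[i]] != family[m[i]]) next
        for (off in c(1:10, -(1:10))) {
          j <- i + off
          if (j < 1 || j > length(f)) next
          if (family[f[i]] != family[m[j]] && family[f[j]] != family[m[i]]) {
            tmp <- m[i]; m[i] <- m[j]; m[j] <- tmp
            break
          }
        }
      }
    }
    list(f = f, m = m)
  }
  if (target_r == 0) {
    perm <- sample(ncpl)
    p <- fix_incest(males, females[perm])
    return(list(father = p$f, mother = p$m,
                realised_r = stats::cor(y[p$f], y[p$m]), noise_sd = Inf))
  }
  sgn <- sign(target_r)
  em <- rnorm(ncpl)
  ef <- rnorm(ncpl)
  pair_of <- function(s) {
    om <- order(y[males] + s * em)
    of <- order(sgn * y[females] + s * ef)
    list(f = males[om], m = females[of])
  }
  r_at <- function(s) { p <- pair_of(s); stats::cor(y[p$f], y[p$m]) }
  tgt <- abs(target_r)
  lo <- 0; hi <- 1
  if (r_at(lo) > tgt) {
    while (r_at(hi) > tgt && hi < 64) hi <- hi * 2
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (r_at(mid) > tgt) lo <- mid else hi <- mid
    }
  } else hi <- 0  # target above the maximum attainable: use exact rank matching
  s <- (lo + hi) / 2
  p <- pair_of(s)
  p <- fix_incest(p$f, p$m)
  list(father = p$f, mother = p$m, realised_r = stats::cor(y[p$f], y[p$m]),
       noise_sd = s)
}

new_pheno_rows <- function(id, generation, a, aa, cval, e) {
  data.frame(id = id, generation = generation, a = a, aa = aa, c = cval, e = e,
             y_raw = a + aa + cval + e)
}

draw_covariates <- function(n, sex) {
  data.frame(sex = sex,
             batch = sample.int(8L, n, replace = TRUE),
             age = sample.int(31L, n, replace = TRUE) + 39L,
             yob = sample.int(34L, n, replace = TRUE) + 1936L)
}

balanced_sex <- function(n) sample(rep(1:2, length.out = n))

#' Simulate a multi-generation cohort under assortative mating
#'
#' Runs the full generator: founder genotypes with designated causal-tag
#' linkage disequilibrium ([simulate_founder_genotypes()]), phenotype
#' construction (additive + epistatic + shared-environment + residual, unit
#' founder variance), and `n_generations` rounds of phenotypic assortative
#' mating with Mendelian transmission by Haldane crossovers on the autosomal
#' genetic map. Interior generations have two offspring per couple (constant
#' population size); the final generation has `sibs_per_family` offspring per
#' couple with optional MZ/DZ twin pairs, and realised genome-wide IBD
#' proportions are recorded for every final-generation sib pair.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cohort`: genotypes for the last
#'   `keep_generations` generations, full pedigree, per-individual phenotype
#'   components, basic covariates, final-generation sib-pair IBD, and a log
#'   with the realised spousal correlation and variance components per
#'   generation.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geno <- simulate_founder_genotypes(config)
  founders <- founder_cohort(geno, config)
  simulate_am_population(founders, config)
}

# Founder-only cohort (generation 0), with phenotypes.
founder_cohort <- function(geno, config) {
  n <- config$n_individuals
  effects <- genetic_effects(geno, config)
  gv <- genetic_values(geno$hapA, geno$hapB, effects)
  cval <- rnorm(n, 0, sqrt(config$c2))
  e <- rnorm(n, 0, sqrt(max(0, 1 - config$h2_rm - config$c2 - config$v_aa)))
  sex <- balanced_sex(n)
  structure(list(
    config = config, effects = effects,
    variant_role = geno$variant_role, allele_freq = geno$allele_freq,
    tag_of = geno$tag_of, position = geno$position, map = geno$map,
    hapA = geno$hapA, hapB = geno$hapB, geno_ids = seq_len(n),
    pedigree = data.frame(id = seq_len(n), father = NA_integer_,
                          mother = NA_integer_, generation = 0L,
                          family = seq_len(n), twin = "", sex = sex),
    pheno = new_pheno_rows(seq_len(n), 0L, gv$a, gv$aa, cval, e),
    covariates = cbind(data.frame(id = seq_len(n)), draw_covariates(n, sex)),
    sib_ibd = NULL,
    log = list(spousal_r = numeric(0), noise_sd = numeric(0),
               var_a = stats::var(gv$a), var_p = stats::var(gv$a + gv$aa + cval + e),
               seed = config$seed)
  ), class = "cohort")
}

#' Breed generations under phenotypic assortative mating
#'
#' @param founders A founder `cohort` (as built inside [simulate_cohort()]).
#' @param config The [sim_config()] used to build it.
#' @return The completed `cohort`; see [simulate_cohort()].
#' @export
simulate_am_population <- function(founders, config) {
  co <- founders
  map <- co$map
  pos <- co$position
  sigma_c <- sqrt(config$c2)
  sigma_e <- sqrt(max(0, 1 - config$h2_rm - config$c2 - config$v_aa))
  next_id <- max(co$pedigree$id) + 1L

  cur <- list(hapA = co$hapA, hapB = co$hapB,
              ids = co$geno_ids,
              y = co$pheno$y_raw, sex = co$pedigree$sex,
              family = co$pedigree$family)
  # generation index + 1 -> haplotypes retained (founders are entry 1)
  gen_keep <- list(list(hapA = co$hapA, hapB = co$hapB, ids = co$geno_ids))

  for (t in seq_len(config$n_generations)) {
    final <- (t == config$n_generations)
    mm <- match_mates(cur$y, cur$sex, config$spousal_r, cur$family)
    ncpl <- length(mm$father)
    if (ncpl < 1) stop("population too small to form families")
    kids_per <- if (final) config$sibs_per_family else config$interior_sibs
    n_off <- ncpl * kids_per
    frep <- rep(mm$father, each = kids_per)
    mrep <- rep(mm$mother, each = kids_per)

    pat <- make_gametes(cur$hapA[frep, , drop = FALSE], cur$hapB[frep, , drop = FALSE],
                        pos, map, keep_recomb = final)
    mat <- make_gametes(cur$hapA[mrep, , drop = FALSE], cur$hapB[mrep, , drop = FALSE],
                        pos, map, keep_recomb = final)
    hapA <- pat$gamete; hapB <- mat$gamete

    fam <- rep(seq_len(ncpl), each = kids_per)
    newfam <- max(co$pedigree$family) + fam
    twin <- rep("", n_off)
    if (final && sum(config$twin_fractions) > 0 && kids_per >= 2) {
      n_mz <- round(config$twin_fractions[["mz"]] * ncpl)
      n_dz <- round(config$twin_fractions[["dz"]] * ncpl)
      pick <- sample(ncpl, min(ncpl, n_mz + n_dz))
      mz_fam <- pick[seq_len(n_mz)]
      dz_fam <- setdiff(pick, mz_fam)
      for (f in mz_fam) {
        i1 <- which(fam == f)[1]; i2 <- i1 + 1L
        hapA[i2, ] <- hapA[i1, ]; hapB[i2, ] <- hapB[i1, ]
        for (cc in seq_along(pat$recomb)) {
          pat$recomb[[cc]] <- copy_owner_recomb(pat$recomb[[cc]], i1, i2)
          mat$recomb[[cc]] <- copy_owner_recomb(mat$recomb[[cc]], i1, i2)
        }
        twin[c(i1, i2)] <- "MZ"
      }
      for (f in dz_fam) twin[which(fam == f)[1:2]] <- "DZ"
    }

    ids <- next_id:(next_id + n_off - 1L)
    next_id <- next_id + n_off
    gv <- genetic_values(hapA, hapB, co$effects)
    cval <- rnorm(ncpl, 0, sigma_c)[fam]
    e <- rnorm(n_off, 0, sigma_e)
    sex <- balanced_sex(n_off)

    co$pedigree <- rbind(co$pedigree, data.frame(
      id = ids, father = cur$ids[frep], mother = cur$ids[mrep],
      generation = t, family = newfam, twin = twin, sex = sex))
    co$pheno <- rbind(co$pheno, new_pheno_rows(ids, t, gv$a, gv$aa, cval, e))
    co$covariates <- rbind(co$covariates,
                           cbind(data.frame(id = ids), draw_covariates(n_off, sex)))
    co$log$spousal_r <- c(co$log$spousal_r, mm$realised_r)
    co$log$noise_sd <- c(co$log$noise_sd, mm$noise_sd)
    co$log$var_a <- c(co$log$var_a, stats::var(gv$a))
    y <- gv$a + gv$aa + cval + e
    co$log$var_p <- c(co$log$var_p, stats::var(y))

    if (final && kids_per >= 2) {
      base <- which(fam == 1L)[1] - 1L  # fam blocks are contiguous
      prs <- utils::combn(seq_len(kids_per), 2)
      i1 <- as.vector(outer(prs[1, ], (seq_len(ncpl) - 1L) * kids_per, `+`))
      i2 <- as.vector(outer(prs[2, ], (seq_len(ncpl) - 1L) * kids_per, `+`))
      ibd <- (recomb_ibd(pat$recomb, i1, i2, map) +
                recomb_ibd(mat$recomb, i1, i2, map)) / 2
      ibd[twin[i1] == "MZ" & twin[i2] == "MZ"] <- 1  # exact by construction
      co$sib_ibd <- data.frame(family = newfam[i1], id1 = ids[i1],
                               id2 = ids[i2], ibd = ibd)
    }

    gen_keep[[t + 1L]] <- list(hapA = hapA, hapB = hapB, ids = ids)
    drop_before <- (t + 1L) - config$keep_generations + 1L
    for (s in seq_len(max(0, drop_before - 1))) gen_keep[s] <- list(NULL)
    cur <- list(hapA = hapA, hapB = hapB, ids = ids, y = y, sex = sex,
                family = newfam)
  }

  keep <- Filter(Negate(is.null), gen_keep)
  co$hapA <- do.call(rbind, lapply(keep, `[[`, "hapA"))
  co$hapB <- do.call(rbind, lapply(keep, `[[`, "hapB"))
  co$geno_ids <- unlist(lapply(keep, `[[`, "ids"))
  co
}

#' (Re)generate phenotypes on a cohort
#'
#' Recomputes additive and epistatic genetic values from the stored genotypes
#' (with the effect sizes and centring constants drawn at founder time) and
#' redraws shared-environment and residual components with the variance
#' fractions in `config`. Shared environment is constant within family;
#' the residual fills the generation-0 variance to 1.
#'
#' @param cohort A `cohort`.
#' @param config A [sim_config()]; defaults to the one stored in the cohort.
#' @return The cohort with its `pheno` table rebuilt for genotyped individuals.
#' @export
generate_phenotypes <- function(cohort, config = cohort$config) {
  rows <- match(cohort$geno_ids, cohort$pedigree$id)
  gv <- genetic_values(cohort$hapA, cohort$hapB, cohort$effects)
  fam <- cohort$pedigree$family[rows]
  cf <- rnorm(length(unique(fam)), 0, sqrt(config$c2))
  cval <- cf[match(fam, unique(fam))]
  sigma_e <- sqrt(max(0, 1 - config$h2_rm - config$c2 - config$v_aa))
  e <- rnorm(length(rows), 0, sigma_e)
  prow <- match(cohort$geno_ids, cohort$pheno$id)
  cohort$pheno[prow, c("a", "aa", "c", "e", "y_raw")] <-
    cbind(gv$a, gv$aa, cval, e, gv$a + gv$aa + cval + e)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  gens <- table(x$pedigree$generation)
  cat("cohort:", nrow(x$pedigree), "individuals in", length(gens), "generations (",
      paste(gens, collapse = "/"), ")\n")
  cat("  genotyped:", length(x$geno_ids), "individuals x",
      length(x$variant_role), "variants;",
      if (!is.null(x$sib_ibd)) nrow(x$sib_ibd) else 0, "sib pairs with IBD\n")
  if (length(x$log$spousal_r))
    cat("  realised spousal r, final generation:",
        round(tail(x$log$spousal_r, 1), 3), "\n")
  invisible(x)
}

#' Ids of genotyped individuals in the most recent generations
#'
#' @param cohort A `cohort`.
#' @param generations Which generation numbers to keep (default: all genotyped).
#' @return Integer vector of individual ids.
#' @export
analysis_ids <- function(cohort, generations = NULL) {
  ids <- cohort$geno_ids
  if (is.null(generations)) return(ids)
  g <- cohort$pedigree$generation[match(ids, cohort$pedigree$id)]
  ids[g %in% generations]
}
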