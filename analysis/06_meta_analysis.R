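# Inverse-variance fixed-effect meta-analysis of the published full-sib IBD
# regression studies (height, BMI, educational attainment), plus the derived
# full-sib correlations, and the assortative-mating adjustment of the height
# meta-analytic heritability back to the equilibrium scale.

source("analysis/00_config.R")

st <- fullsib_studies()
rows <- list()
for (tr in unique(st$trait)) {
  s <- st[st$trait == tr, ]
  mh <- ivw_meta(s$h2, s$h2_se, labels = s$study)
  mc <- ivw_meta(s$c2, s$c2_se, labels = s$study)
  mr <- meta_fullsib_correlation(s)
  rows[[tr]] <- data.frame(trait = tr, n_pair = sum(s$n_pair),
                           h2_fs = mh$estimate, h2_se = mh$se, h2_q = mh$q,
                           c2_fs = mc$estimate, c2_se = mc$se,
                           r_fs = mr$estimate, r_se = mr$se)
}
meta <- do.call(rbind, rows)
print(meta, digits = 3)
write.table(meta, "results/06_meta_analysis.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# adjust the height full-sib meta estimate for assortment (r from spousal
# correlation estimates for height) back to the equilibrium heritability
h <- meta[meta$trait == "height", ]
adj <- equilibrium_from_design(h$h2_fs, r = 0.24, se_h2 = h$h2_se, se_r = 0.04)
cat(sprintf("height: meta h2_FS = %.2f (se %.2f) -> h2_EQ = %.2f (se %.2f) at r = 0.24\n",
            h$h2_fs, h$h2_se, adj$h2_eq, adj$se))
write.table(data.frame(trait = "height", h2_fs = h$h2_fs, r = 0.24,
                       h2_eq_adjusted = adj$h2_eq, se = adj$se),
            "results/06_am_adjusted.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
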