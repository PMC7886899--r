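# Simulate the working cohort: six generations of phenotypic assortative
# mating (target spousal correlation 0.24) over an AE architecture with
# h2 = 0.7 under random mating. Writes the cohort tables and the
# per-generation variance log.

source("analysis/00_config.R")

co <- analysis_cohort()
print(co)

log_tab <- data.frame(
  generation = seq_along(co$log$var_a) - 1L,
  var_additive = co$log$var_a,
  var_phenotype = co$log$var_p,
  spousal_r = c(NA, co$log$spousal_r)
)
write.table(log_tab, "results/01_generation_log.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

write.table(co$pedigree, "results/01_pedigree.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(co$pheno, "results/01_phenotypes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(co$sib_ibd, "results/01_sib_ibd.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("additive variance rose from %.3f to %.3f over %d generations (plateau expected)\n",
            co$log$var_a[1], tail(co$log$var_a, 1), length(co$log$spousal_r)))
cat(sprintf("realised spousal correlation in the final generation: %.3f\n",
            tail(co$log$spousal_r, 1)))
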