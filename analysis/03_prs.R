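#!/usr/bin/env Rscript
# Stage 2: load of trait-B risk alleles in trait-A cases vs controls.
# Three non-LD-pruned risk-SNP tiers from the trait-B summary statistics
# (strong 5e-8, moderate 1e-4, weak 1e-2), per-individual weighted allele
# scores, and a logistic model of trait-A status on the standardized score,
# adjusted for sex and cohort.

source("analysis/00_setup.R")

panel <- build_panel()
arch <- build_arch(panel)
ss <- build_sumstats(panel, arch)
cohort <- build_cohort(panel, arch)

message(sprintf("cohort: %d cases / %d controls across %d sub-cohorts",
                sum(cohort$phenotype), sum(1 - cohort$phenotype), COHORT_K))

tiers <- prs_tiers(cohort, ss$b,
                   thresholds = c(strong = 5e-8, moderate = 1e-4, weak = 1e-2))
out <- transform(tiers, or = signif(or, 4), ci_low = signif(ci_low, 4),
                 ci_high = signif(ci_high, 4), p = signif(p, 3))
write_tsv(out, "results/prs_results.tsv")
print(out, row.names = FALSE)

for (i in seq_len(nrow(tiers))) {
  dir <- if (is.na(tiers$or[i])) "undetermined" else if (tiers$or[i] < 1) {
    "protective"
  } else "risk-increasing"
  message(sprintf("tier %-8s (%d SNPs): trait-B score is %s for trait A (OR %.3f, p %.2g)",
                  tiers$tier[i], tiers$n_snps[i], dir, tiers$or[i], tiers$p[i]))
}
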