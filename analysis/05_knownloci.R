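#!/usr/bin/env Rscript
# Stage 4: cross-query of each trait's established lead SNPs (here, the
# planted causal SNPs of each trait's loci) against the other trait's summary
# statistics, Bonferroni-correcting within each family for the number of SNPs
# actually testable.

source("analysis/00_setup.R")

panel <- build_panel()
arch <- build_arch(panel)
ss <- build_sumstats(panel, arch)

lead_table <- function(beta_vec) {
  idx <- which(beta_vec != 0)
  data.frame(snp_id = panel$map$snp_id[idx],
             effect_allele = panel$map$effect_allele[idx],
             other_allele = panel$map$other_allele[idx],
             beta = beta_vec[idx], stringsAsFactors = FALSE)
}
leads_a <- lead_table(arch$beta_a)   # trait-A "reported" loci (incl. shared)
leads_b <- lead_table(arch$beta_b)

qa <- cross_query(leads_a, ss$b, family_alpha = 0.05)
qb <- cross_query(leads_b, ss$a, family_alpha = 0.05)

summarize <- function(q, from, to) {
  message(sprintf("%s leads in %s: %d/%d testable, threshold %.2g; %d significant, %d of those direction-concordant",
                  from, to, q$n_testable, q$n_testable + nrow(q$excluded),
                  q$bonferroni_alpha, sum(q$results$significant),
                  sum(q$results$direction_agreement & q$results$significant)))
  cbind(source = from, q$results)
}
out <- rbind(summarize(qa, "trait_a", "trait_b"),
             summarize(qb, "trait_b", "trait_a"))
out$p <- signif(out$p, 3)
out$beta <- signif(out$beta, 3)
write_tsv(out, "results/knownloci.tsv")
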