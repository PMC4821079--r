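# Shared study configuration for the analysis scripts. Sourced by each
# numbered driver; everything regenerates deterministically from SEED, so no
# large intermediates need to be written to disk.

library(pleiomap)

SEED <- 42
dir.create("results", showWarnings = FALSE)

# genome: 100 AR(1) LD blocks of 50 SNPs (5,000 SNPs) over 5 chromosomes,
# 200 reference individuals
PANEL_SPEC <- ld_block_spec(n_blocks = 100, snps_per_block = 50,
                            within_block_rho = 0.8, maf_range = c(0.05, 0.5),
                            n_chrom = 5)

# study sample sizes: two large case/control GWAS, two subtype GWAS of trait
# A, and an individual-level trait-A cohort
N_A <- c(19981, 56667)
N_B <- c(21076, 63014)
N_SUB1 <- c(6413, 32745)   # subtype with the shared component
N_SUB2 <- c(4940, 37557)   # subtype without it
# individual-level cohort at the study's scale: 6,350 cases / 15,069 controls
# across 6 sub-cohorts (per-allele effects realistic for GWAS loci are small,
# so the score-load contrast needs a cohort of this size to be visible)
COHORT_N <- 21419
COHORT_PREV <- 6350 / 21419
COHORT_K <- 6

build_panel <- function() simulate_panel(PANEL_SPEC, 200, seed = SEED)

# architecture: 16 shared causal loci (10 with opposite effect direction in
# the two traits, 6 concordant), 7 loci specific to trait A and 15 specific
# to trait B; per-locus non-centralities drawn once in 5-9
build_arch <- function(panel) {
  set.seed(SEED + 1)
  shared_blocks <- seq(3, 93, by = 6)          # 16 blocks (all odd)
  b_blocks <- seq(2, 58, by = 4)               # 15 trait-B-specific (even)
  a_blocks <- seq(60, 84, by = 4)              # 7 trait-A-specific (even)
  mid_maf <- function(blocks) {
    vapply(blocks, function(b) panel$map$maf[which(panel$map$block == b)[25]], 0)
  }
  opp <- c(rep(-1, 10), rep(1, 6))[sample.int(16)]
  ncp_sh <- runif(16, 5, 9)
  shared <- data.frame(
    block = shared_blocks,
    beta_a = beta_for_ncp(ncp_sh, mid_maf(shared_blocks), N_A[1], N_A[2]),
    beta_b = opp * beta_for_ncp(ncp_sh, mid_maf(shared_blocks), N_B[1], N_B[2]))
  a_loci <- data.frame(block = a_blocks,
                       beta = beta_for_ncp(runif(length(a_blocks), 5, 9),
                                           mid_maf(a_blocks), N_A[1], N_A[2]))
  b_loci <- data.frame(block = b_blocks,
                       beta = beta_for_ncp(runif(length(b_blocks), 5, 9),
                                           mid_maf(b_blocks), N_B[1], N_B[2]))
  architecture(panel, shared_loci = shared, trait_a_loci = a_loci,
               trait_b_loci = b_loci)
}

build_sumstats <- function(panel, arch) {
  simulate_sumstats_pair(panel, arch, n_a = N_A, n_b = N_B, seed = SEED + 2)
}

# subtype tables: subtype 1 carries the trait-A architecture at full strength,
# subtype 2 attenuated, with identical effect directions
build_subtypes <- function(panel, arch) {
  sub_arch <- architecture(panel)
  sub_arch$beta_a <- 1.15 * arch$beta_a
  sub_arch$beta_b <- 0.70 * arch$beta_a
  simulate_sumstats_pair(panel, sub_arch, n_a = N_SUB1, n_b = N_SUB2,
                         seed = SEED + 3)
}

build_cohort <- function(panel, arch) {
  simulate_cohort(panel, arch, n = COHORT_N, prevalence = COHORT_PREV,
                  n_cohorts = COHORT_K, trait = "a", seed = SEED + 4)
}

build_pair <- function(panel, arch) {
  ss <- build_sumstats(panel, arch)
  align_alleles(ss$a, ss$b)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
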