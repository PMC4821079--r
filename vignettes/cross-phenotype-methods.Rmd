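---
title: "Cross-phenotype GWAS analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-phenotype GWAS analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomap)
```

# Scope

`pleiomap` asks, for a pair of complex traits studied in two non-overlapping
GWAS: do the traits share genetic risk variants, in which direction, and
where? It answers with four complementary stages over harmonized summary
statistics — overlap enrichment, polygenic risk-score loading, a spatial
covariance scan, and a known-locus cross-query — plus a synthetic-data module
that generates every input with a known ground truth, so each stage's
operating characteristics can be verified end to end.

This vignette documents the statistical model of each stage, the tunable
parameters with their defaults and rationale, the numerical and design
choices made where the design was genuinely open, and the known limitations,
including exactly what the simulation-based tests do and do not demonstrate
about real data.

# Input model and harmonization

Each GWAS is a table of per-SNP association results: identifier, position,
effect and other allele, log odds ratio $\hat\beta$, its standard error, a
p-value in $(0, 1]$, and study sample sizes. Validation drops rows violating
these domain constraints (counted by reason, with line numbers reported) and
sorts by position.

The two tables are inner-joined on SNP identifier. Study B's effect is mapped
onto study A's allele orientation with at most one effect/other swap and one
strand complement; a swap negates $\hat\beta_B$ and is recorded in a
`flipped` flag. Three choices here were open and are package decisions:

* **Join key.** rsID, not position: the intended inputs are imputed to a
  common reference, where identifiers are shared. Records whose positions
  disagree between studies are dropped, not reconciled.
* **Palindromic SNPs.** A/T and C/G variants cannot be strand-resolved
  without allele frequencies, which summary tables may lack; they are dropped
  by default (`drop_palindromic = TRUE`). Retaining them assumes both studies
  report the same strand.
* **Accounting.** Every study-B record is classified exactly once:
  harmonized, non-overlapping, discordant position, palindromic, or allele
  mismatch; the counts must sum to the input size (tested as an invariant).

# Stage 1: overlap of association signals

SNPs are first thinned to approximate linkage equilibrium by the classical
greedy rule: sort by association p-value in the ordering trait (trait A by
default), keep the best remaining SNP, discard every remaining SNP with
$r^2 > 0.05$ to it, repeat. Ties in p are broken by position so the output is
deterministic and invariant to row order. The $r^2$ source is either a
reference panel's dosages (squared Pearson correlation, zero across LD
blocks) or a user-supplied pairwise table.

For each p-value cutoff $c \in \{10^{-2}, \ldots, 10^{-6}\}$ the pruned SNPs
form a 2×2 table (below/above $c$ in each trait), tested with the two-sided
Fisher exact test and adjusted across the scan with Benjamini–Hochberg; a
corrected $p < 0.01$ flags an excess of shared signals. The number of tests
adjusted together equals the number of cutoffs configured.

An empirical permutation p complements the exact test: each cycle shuffles
the SNP-to-p assignment independently within each trait's pruned vector and
recomputes the Fisher p per cutoff. Because shuffling preserves both margins,
only the joint count $n_{11}$ varies, and the implementation precomputes the
Fisher p as a lookup over $n_{11}$ — the permutations themselves are still
performed literally. The estimator is the add-one form
$(1 + \#\{p^\ast \le p_{obs}\})/(B + 1)$, which cannot return zero.

Direction concordance among doubly-significant SNPs is tested against 0.5
with the exact two-tailed binomial test (minimum-likelihood two-sided
convention, i.e. the sum of all outcome probabilities not exceeding the
observed one; for 12 of 16 this gives 0.0768, printing as 0.08).

**Numerical note.** `fisher_two_sided()` computes the exact two-sided p
directly as a hypergeometric tail sum with the same $1 + 10^{-7}$ relative
tie tolerance R's exact tests use; `stats::fisher.test` serves as an
independent cross-check in the test suite (exhaustively, for every table with
total ≤ 40). The odds ratio reported is the sample odds ratio
$n_{11}n_{00}/(n_{10}n_{01})$, flagged when a zero cell makes it undefined.

# Stage 2: polygenic risk-score loading

Three risk-SNP tiers are selected from the discovery trait at
$p \le 5\times10^{-8}$ (strong), $10^{-4}$ (moderate), $10^{-2}$ (weak) —
deliberately not LD-pruned, which maximizes sensitivity at the cost of
redundant weight on long haplotypes. Each individual's score is
$\sum_j d_{ij} w_j$ over the tier's SNPs, with dosages reconciled to the
tier's effect alleles ($d \mapsto 2 - d$ when the cohort counts the other
allele); absent or irreconcilable SNPs are skipped and counted, and a tier
more than half unusable is flagged.

Association is a logistic regression of case status on the score, adjusted
for sex and reference-coded cohort indicators. Open choices:

* the score is standardized to unit SD first, so the odds ratio has a
  defined per-1-SD scale;
* Wald intervals and p-values (profile likelihood adds nothing at the
  simulated sample sizes and is much slower);
* missing dosages are skipped for that individual, never mean-imputed, with
  per-individual missingness reported;
* constant covariates are dropped with a warning; apparent separation or
  non-convergence yields a flagged result with no estimate rather than a
  misleading one.

# Stage 3: cross-phenotype spatial mapping

The scan looks for genomic regions where the two traits' association
profiles covary. The realization here is stated in full because only the
idea — covariance of two p-value profiles, thresholded at the 99.95th
percentile of 1,000 permutations, yielding regions with per-trait lead
SNPs — was fixed in advance:

1. **Transform.** Per trait, $-\log_{10} p$, then rank-normalized within
   chromosome (average ranks mapped through $\Phi^{-1}(r/(n+1))$). Rank
   normalization makes the window statistic invariant to any strictly
   monotone transform of either trait's p-values and robust to their very
   different tail behavior. P-values below a floor (default $10^{-30}$) are
   clamped first.
2. **Scan.** Sliding windows of 100 SNPs advancing by 50, never spanning
   chromosomes; windows with fewer than 10 SNPs are not emitted. The window
   statistic is the sample covariance of the two transformed profiles.
3. **Null.** Each permutation circularly rotates one trait's profile by a
   random offset within each chromosome, preserving each trait's local
   autocorrelation (from LD) while breaking only the cross-trait alignment;
   the threshold is the 99.95th percentile of the pooled null statistics. A
   full within-chromosome shuffle is available for comparison
   (`mode = "shuffle"`); it destroys autocorrelation and is anticonservative
   in LD-dense data.
4. **Regions.** Significant windows overlapping or within 50 kb merge into
   regions; each region reports its peak statistic, each trait's lead SNP
   (smallest p inside the region) with its harmonized effect, and whether
   the two lead effects share sign.

Subtype annotation looks up each region's trait-A lead in two subtype
tables, aligns their effects to the pair's orientation, counts leads with a
strictly lower p in the first subtype (ties conservatively count as "not
lower"), and tests that count against 0.5 with the exact binomial test.

**Known behavior of the rotation null.** When planted (or real) shared
signal is dense relative to the genome scanned, rotations frequently land
one trait's peaks on the other's, inflating the pooled percentile: the scan
becomes conservative. The contamination fraction scales roughly as
$(\text{window} + \text{block})^2 / L^2$ for a chromosome of $L$ SNPs, so it
is negligible at genome-wide densities but visible in toy genomes. The
detection tests therefore use a single 8,000-SNP chromosome with one planted
locus, where the 99.95th percentile sits in the clean null; the analysis
scripts, which deliberately plant 16 loci in 5,000 SNPs, print both the
rotation and shuffle thresholds and recover only the strongest loci — that
is the method behaving as designed, not failing.

# Stage 4: known-locus cross-query

Each trait's previously established lead SNPs are looked up in the other
trait's table. Leads absent from the table (or with irreconcilable alleles)
are excluded from the Bonferroni denominator — the per-SNP threshold is
`family_alpha / n_testable`, never looser than the family alpha — and each
trait's family is corrected separately. The family alpha defaults to 0.05.
Proxy-SNP substitution for unavailable leads is deliberately out of scope.

# The synthetic-data module

The generator emulates the three inputs the analysis needs:

* **Reference panel.** Haplotypes are latent AR(1) Gaussians per LD block
  (correlation `within_block_rho` between adjacent SNPs, default 0.8 in the
  analysis scripts), thresholded at $\Phi^{-1}(\mathrm{MAF})$ with per-SNP
  MAFs uniform on (0.05, 0.5); dosage is the sum of two haplotypes. LD is
  therefore block-diagonal with geometric decay — simple, controllable, and
  sufficient for exercising greedy pruning and windowed covariance.
* **Summary statistics.** Marginal z-scores per block follow the standard
  model $z \sim \mathcal{N}(R\lambda, R)$, with $R$ the block's dosage
  correlation from the panel and $\lambda_j = \beta_j/\mathrm{se}_j$,
  $\mathrm{se}_j = \sqrt{(1/n_{cases} + 1/n_{controls})/(2f_j(1-f_j))}$.
  Then $\hat\beta = z \cdot \mathrm{se}$ and $p = 2\Phi(-|z|)$.
  `beta_for_ncp()` inverts this to plant a locus at a chosen non-centrality;
  the effect must be sized at the causal SNP's own MAF, since the same
  log-OR corresponds to very different non-centralities at different
  frequencies. A singular block correlation is ridge-stabilized with a
  warning. Default sample sizes are the two large case/control studies the
  package's analyses emulate (19,981/56,667 and 21,076/63,014).
* **Cohorts.** Liability equals dosage-weighted true effects plus standard
  normal noise; individuals above the empirical $(1-\text{prevalence})$
  quantile are cases, so realized prevalence is exact. Sex and cohort labels
  are uniform. Defaults: 21,419 individuals at prevalence 6350/21419 in 6
  sub-cohorts.

All randomness flows from explicit integer seeds; identical seeds give
byte-identical outputs, and the pipeline derives an independent substream
per stage so toggling one stage never perturbs another's draws.

What the generator does **not** emulate: coalescent/demographic structure,
allele-frequency differences between studies, imputation uncertainty,
genotyping batch effects, cryptic relatedness, or the X chromosome. Passing
tests therefore demonstrate the algorithms' correctness and calibration
under an idealized LD model, not robustness to those artifacts.

# Problem sizes used by the tests and acceptance runs

Chosen to make every property measurable on a single core in minutes:

* null calibration: 20 replicate studies of 5,000 SNPs (100 blocks × 50,
  5 chromosomes, 200 reference individuals), 1,000 permutations each for the
  window threshold; overlap flags expected in at most one replicate, window
  exceedances within a 3-SE binomial band of 5×10⁻⁴;
* score recovery: cohorts of n = 2,000 with eight planted protective loci
  (liability effects −0.18) must fit OR < 1 in ≥ 95% of 20 replicates; under
  a null architecture the 95% CI must cover 1.0 in 90–100% of 50 replicates;
* scan detection: one locus at non-centrality 8 in a 50-SNP block of an
  8,000-SNP chromosome, recovered as a region in ≥ 90% of 10 replicates with
  the planted sign relation every time;
* exactness: the Fisher p is compared with `stats::fisher.test` on all
  135,750 tables with total ≤ 40; greedy pruning against a literal
  re-execution of its rule on 1,000 random 50-SNP instances.

The detection margin is real: measured recovery is ≈ 92% under these
conditions, so an unlucky replicate batch can score 8/10. The conditions are
fixed; the margin is reported, not widened.

# Limitations

* Rank normalization compresses extreme association peaks to the largest
  normal quantile ($\approx \Phi^{-1}(n/(n+1))$), costing power for isolated
  single-SNP signals with little LD support; that is the price of the
  transform's robustness.
* The rotation null's conservatism under dense signal (above).
* Fisher's exact test and the binomial test inherit the
  sum-of-small-probabilities two-sided convention; other conventions
  (doubling the one-sided p) give different values.
* Wald intervals undercover slightly at small n or extreme prevalence.
* The greedy pruning rule is order-dependent by design — it is the stated
  procedure, not an optimal independent-set solver.
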