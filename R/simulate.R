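# Synthetic GWAS data: LD-structured reference panels, two-trait summary
# statistics under a configurable shared architecture, and liability-threshold
# case/control cohorts. Every analysis stage can therefore be exercised with a
# known ground truth.

#' Specify a block-diagonal AR(1) LD structure
#'
#' LD is modelled as independent blocks; within a block the latent haplotype
#' Gaussian has AR(1) correlation `within_block_rho` between adjacent SNPs, so
#' dosage r2 decays geometrically with SNP distance and is exactly zero across
#' blocks.
#'
#' @param n_blocks Number of independent LD blocks (>= 1).
#' @param snps_per_block SNPs per block (>= 1).
#' @param within_block_rho Latent AR(1) correlation between adjacent SNPs,
#'   in `[0, 1)`.
#' @param maf_range Minor-allele-frequency range `(low, high)` with
#'   `0 < low <= high <= 0.5`; per-SNP MAFs are drawn uniformly from it.
#' @param n_chrom Number of chromosomes (1-22) the blocks are distributed
#'   over, in contiguous runs.
#' @return An `ld_block_spec` list.
#' @export
ld_block_spec <- function(n_blocks, snps_per_block, within_block_rho,
                          maf_range = c(0.05, 0.5), n_chrom = 1L) {
  stopifnot(n_blocks >= 1, snps_per_block >= 1,
            within_block_rho >= 0, within_block_rho < 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[2] <= 0.5, n_chrom >= 1, n_chrom <= 22,
            n_chrom <= n_blocks)
  if (maf_range[1] <= 0) stop("maf_range lower bound must be > 0")
  structure(list(n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 within_block_rho = within_block_rho,
                 maf_range = maf_range,
                 n_chrom = as.integer(n_chrom)),
            class = "ld_block_spec")
}

# Draw an n x m dosage matrix: two latent-AR(1) haplotypes per individual,
# thresholded at qnorm(maf) so allele frequency equals maf in expectation.
simulate_dosages <- function(spec, maf, n) {
  m <- spec$n_blocks * spec$snps_per_block
  stopifnot(length(maf) == m)
  rho <- spec$within_block_rho
  k <- spec$snps_per_block
  dos <- matrix(0, n, m)
  for (b in seq_len(spec$n_blocks)) {
    idx <- ((b - 1L) * k + 1L):(b * k)
    thr <- matrix(stats::qnorm(maf[idx]), n, k, byrow = TRUE)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n * k), n, k)
      if (k > 1 && rho > 0) {
        for (j in 2:k) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      dos[, idx] <- dos[, idx] + (z < thr)
    }
  }
  dos
}

#' Simulate an LD reference panel
#'
#' Draws `n_individuals` diploid dosages under the block AR(1) haplotype model
#' of [ld_block_spec()]. The panel stands in for an external haplotype
#' reference panel as the source of pairwise r2 for pruning and for the LD
#' matrix used when simulating summary statistics.
#'
#' @param spec An `ld_block_spec`.
#' @param n_individuals Number of reference individuals (>= 2).
#' @param seed Integer seed; the panel is deterministic given `(spec, seed)`.
#' @return A `ref_panel` list: `dosage` (individuals x SNPs, values 0/1/2),
#'   `map` (snp_id, chrom, pos, effect_allele, other_allele, block, maf),
#'   `spec`, `seed`.
#' @export
simulate_panel <- function(spec, n_individuals, seed) {
  stopifnot(inherits(spec, "ld_block_spec"), n_individuals >= 2)
  set.seed(seed)
  m <- spec$n_blocks * spec$snps_per_block
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  dosage <- simulate_dosages(spec, maf, n_individuals)

  # non-palindromic allele pairs so harmonization keeps everything by default
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  al <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]

  blocks_per_chrom <- ceiling(spec$n_blocks / spec$n_chrom)
  block <- rep(seq_len(spec$n_blocks), each = spec$snps_per_block)
  chrom <- (block - 1L) %/% blocks_per_chrom + 1L
  within <- rep(seq_len(spec$snps_per_block), times = spec$n_blocks)
  block_in_chrom <- (block - 1L) %% blocks_per_chrom
  # 5 kb SNP spacing within a block, 100 kb gap between blocks
  pos <- block_in_chrom * (spec$snps_per_block * 5000 + 100000) +
    (within - 1L) * 5000 + 1

  map <- data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
                    chrom = as.integer(chrom), pos = as.numeric(pos),
                    effect_allele = al[, 1], other_allele = al[, 2],
                    block = block, maf = maf, stringsAsFactors = FALSE)
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, spec = spec, seed = seed),
            class = "ref_panel")
}

#' Pairwise r2 within each LD block of a panel
#'
#' Squared Pearson correlation of dosages for every SNP pair within a block;
#' cross-block r2 is zero by construction and is not materialized.
#'
#' @param panel A `ref_panel`.
#' @return List of per-block matrices (SNP ids as dimnames). Monomorphic SNPs
#'   yield r2 0 against everything (r2 with itself is set to 1).
#' @export
panel_r2 <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  lapply(split(seq_len(nrow(panel$map)), panel$map$block), function(idx) {
    r <- suppressWarnings(stats::cor(panel$dosage[, idx, drop = FALSE]))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    r^2
  })
}

#' Define a two-trait genetic architecture over a panel
#'
#' True per-SNP effects (log-odds-ratio / liability scale) for two traits.
#' Shared loci place a causal SNP (the middle SNP of the named block) with an
#' effect on both traits; trait-specific loci affect exactly one trait; an
#' optional polygenic background adds independent Gaussian effects to every
#' SNP.
#'
#' @param panel A `ref_panel`.
#' @param shared_loci Data frame with columns `block`, `beta_a`, `beta_b`
#'   (one row per shared causal locus), or `NULL`.
#' @param trait_a_loci,trait_b_loci Data frames with columns `block`, `beta`
#'   for trait-specific causal loci, or `NULL`.
#' @param polygenic_sd Length-2 numeric `(trait A, trait B)`: standard
#'   deviation of per-SNP background effects (0 disables).
#' @param seed Seed for drawing the polygenic background (required if any
#'   `polygenic_sd` > 0).
#' @return An `architecture` list: `beta_a`, `beta_b` (length = panel SNPs),
#'   `shared` (with the causal `snp_id` resolved), and
#'   `direction_concordance` (fraction of shared loci with same-sign effects,
#'   `NA` if none).
#' @export
architecture <- function(panel, shared_loci = NULL, trait_a_loci = NULL,
                         trait_b_loci = NULL, polygenic_sd = c(0, 0),
                         seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"), length(polygenic_sd) == 2)
  m <- nrow(panel$map)
  beta_a <- numeric(m)
  beta_b <- numeric(m)
  mid_snp <- function(block) {
    idx <- which(panel$map$block == block)
    if (!length(idx)) stop("architecture references invalid block ", block)
    idx[ceiling(length(idx) / 2)]
  }
  shared <- NULL
  if (!is.null(shared_loci) && nrow(shared_loci)) {
    stopifnot(all(c("block", "beta_a", "beta_b") %in% names(shared_loci)))
    ci <- vapply(shared_loci$block, mid_snp, 0L)
    beta_a[ci] <- beta_a[ci] + shared_loci$beta_a
    beta_b[ci] <- beta_b[ci] + shared_loci$beta_b
    shared <- cbind(shared_loci,
                    snp_index = ci, snp_id = panel$map$snp_id[ci],
                    stringsAsFactors = FALSE)
  }
  add_specific <- function(beta, loci) {
    if (is.null(loci) || !nrow(loci)) return(beta)
    stopifnot(all(c("block", "beta") %in% names(loci)))
    ci <- vapply(loci$block, mid_snp, 0L)
    beta[ci] <- beta[ci] + loci$beta
    beta
  }
  beta_a <- add_specific(beta_a, trait_a_loci)
  beta_b <- add_specific(beta_b, trait_b_loci)
  if (any(polygenic_sd > 0)) {
    if (is.null(seed)) stop("seed required when polygenic_sd > 0")
    set.seed(derive_seed(seed, 97L))
    beta_a <- beta_a + stats::rnorm(m, 0, polygenic_sd[1])
    beta_b <- beta_b + stats::rnorm(m, 0, polygenic_sd[2])
  }
  dc <- if (!is.null(shared)) {
    mean(sign(shared$beta_a) == sign(shared$beta_b))
  } else NA_real_
  structure(list(beta_a = beta_a, beta_b = beta_b, shared = shared,
                 direction_concordance = dc, polygenic_sd = polygenic_sd),
            class = "architecture")
}

#' Null architecture: no genetic effects on either trait
#' @param panel A `ref_panel`.
#' @return An `architecture` with all effects zero.
#' @export
null_architecture <- function(panel) architecture(panel)

#' Log-odds-ratio giving a target GWAS non-centrality
#'
#' Inverts the standard summary-statistic model: the expected z-score at a
#' causal SNP is `beta / se` with
#' `se = sqrt((1/n_cases + 1/n_controls) / (2 f (1 - f)))`, so the log-OR that
#' yields non-centrality `ncp` is `ncp * se`.
#'
#' @param ncp Target non-centrality (expected z at the causal SNP).
#' @param maf Allele frequency `f`.
#' @param n_cases,n_controls Study sample sizes.
#' @return Log odds ratio.
#' @export
beta_for_ncp <- function(ncp, maf, n_cases, n_controls) {
  ncp * sqrt((1 / n_cases + 1 / n_controls) / (2 * maf * (1 - maf)))
}

#' Simulate a pair of GWAS summary-statistics tables
#'
#' Marginal association z-scores for each trait are drawn from the standard
#' summary-statistics model `z ~ MVN(R lambda, R)` per LD block, where `R` is
#' the block's dosage correlation matrix from the panel and
#' `lambda_j = beta_j / se_j` is the per-SNP non-centrality implied by the
#' true effect and the study's sample sizes. Reported `beta = z * se`,
#' `p = 2 * pnorm(-|z|)`. Default sample sizes are a large two-study
#' case/control setting (19,981/56,667 and 21,076/63,014).
#'
#' @param panel A `ref_panel`.
#' @param arch An `architecture` over the same panel.
#' @param n_a,n_b Length-2 `(cases, controls)` for traits A and B.
#' @param seed Integer seed; deterministic given all arguments.
#' @return List with elements `a` and `b`, each a validated `sumstats`.
#' @export
simulate_sumstats_pair <- function(panel, arch,
                                   n_a = c(19981, 56667),
                                   n_b = c(21076, 63014), seed) {
  stopifnot(inherits(panel, "ref_panel"), inherits(arch, "architecture"),
            length(n_a) == 2, length(n_b) == 2)
  set.seed(seed)
  m <- nrow(panel$map)
  f <- pmin(pmax(colMeans(panel$dosage) / 2, 0.005), 0.995)
  blocks <- split(seq_len(m), panel$map$block)
  chol_list <- vector("list", length(blocks))
  R_list <- vector("list", length(blocks))
  ridged <- FALSE
  for (i in seq_along(blocks)) {
    idx <- blocks[[i]]
    R <- suppressWarnings(stats::cor(panel$dosage[, idx, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    ch <- tryCatch(chol(R), error = function(e) NULL)
    eps <- 1e-8
    while (is.null(ch) && eps <= 1e-2) {
      ridged <- TRUE
      ch <- tryCatch(chol((R + diag(eps, nrow(R))) / (1 + eps)),
                     error = function(e) NULL)
      eps <- eps * 10
    }
    if (is.null(ch)) stop("LD block ", i, " correlation not stabilizable")
    R_list[[i]] <- R
    chol_list[[i]] <- ch
  }
  if (ridged) warning("singular LD block correlation ridge-stabilized")

  one_trait <- function(beta_true, n_cc) {
    neff <- c(n_cc[1], n_cc[2])
    se <- sqrt((1 / neff[1] + 1 / neff[2]) / (2 * f * (1 - f)))
    lambda <- beta_true / se
    z <- numeric(m)
    for (i in seq_along(blocks)) {
      idx <- blocks[[i]]
      mu <- drop(R_list[[i]] %*% lambda[idx])
      z[idx] <- mu + drop(crossprod(chol_list[[i]], stats::rnorm(length(idx))))
    }
    p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    df <- data.frame(panel$map[, c("snp_id", "chrom", "pos",
                                   "effect_allele", "other_allele")],
                     beta = z * se, se = se, p = p,
                     n_cases = n_cc[1], n_controls = n_cc[2],
                     stringsAsFactors = FALSE)
    as_sumstats(df)
  }
  a <- one_trait(arch$beta_a, n_a)
  b <- one_trait(arch$beta_b, n_b)
  list(a = a, b = b)
}

#' Simulate an individual-level case/control cohort
#'
#' Dosages are drawn under the panel's haplotype model (same MAFs and LD
#' blocks); liability is `dosage %*% beta + N(0, 1)` noise using the selected
#' trait's true effects; individuals above the empirical `(1 - prevalence)`
#' liability quantile are cases. Sex (0/1) and a cohort label (1..n_cohorts)
#' are assigned uniformly. Defaults mirror a multi-cohort case/control
#' setting of 6,350 cases / 15,069 controls across 6 cohorts.
#'
#' @param panel A `ref_panel` (defines SNPs, MAFs and LD).
#' @param arch An `architecture`; `trait` selects which trait's effects drive
#'   liability.
#' @param n Number of individuals.
#' @param prevalence Case fraction in `(0, 1)`.
#' @param n_cohorts Number of cohort labels (>= 1).
#' @param trait `"a"` or `"b"`.
#' @param seed Integer seed.
#' @return A `cohort` list: `dosage` (n x SNPs), `map` (snp_id and the counted
#'   effect allele), `phenotype` (0/1), `sex` (0/1), `cohort_label` (factor),
#'   `seed`.
#' @export
simulate_cohort <- function(panel, arch, n = 21419,
                            prevalence = 6350 / 21419, n_cohorts = 6,
                            trait = c("a", "b"), seed) {
  stopifnot(inherits(panel, "ref_panel"), inherits(arch, "architecture"),
            prevalence > 0, prevalence < 1, n_cohorts >= 1)
  trait <- match.arg(trait)
  if (n * prevalence < 1 || n * (1 - prevalence) < 1) {
    stop("n too small to contain at least one case and one control")
  }
  set.seed(seed)
  beta <- if (trait == "a") arch$beta_a else arch$beta_b
  dosage <- simulate_dosages(panel$spec, panel$map$maf, n)
  colnames(dosage) <- panel$map$snp_id
  liability <- drop(dosage %*% beta) + stats::rnorm(n)
  thr <- stats::quantile(liability, 1 - prevalence)
  phenotype <- as.integer(liability > thr)
  if (sum(phenotype) == 0L || sum(phenotype) == n) {
    stop("degenerate cohort: no cases or no controls")
  }
  structure(list(dosage = dosage,
                 map = panel$map[, c("snp_id", "chrom", "pos",
                                     "effect_allele", "other_allele")],
                 phenotype = phenotype,
                 sex = stats::rbinom(n, 1, 0.5),
                 cohort_label = factor(sample.int(n_cohorts, n, replace = TRUE)),
                 seed = seed),
            class = "cohort")
}
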