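# --- greedy LD pruning ----------------------------------------------------

test_that("pruning keeps everything when all SNPs are independent", {
  pair <- make_pair(paste0("s", 1:5), p_a = c(.5, .1, .3, .2, .4), p_b = runif(5))
  r2 <- data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0))
  pruned <- ld_prune(pair, r2_table = r2)
  expect_setequal(pruned$snp_id, pair$snp_id)
  # selection order is ascending p in the ordering trait
  expect_equal(pruned$snp_id, pair$snp_id[order(pair$p_a)])
})

test_that("of two perfectly correlated SNPs only the smaller-p one survives", {
  pair <- make_pair(c("s1", "s2"), p_a = c(0.2, 0.01), p_b = c(0.5, 0.5))
  r2 <- data.frame(snp_a = "s1", snp_b = "s2", r2 = 1)
  pruned <- ld_prune(pair, r2_table = r2)
  expect_equal(pruned$snp_id, "s2")
})

test_that("6-SNP toy matches the hand-applied greedy rule", {
  # hand enumeration: take s1 (p=.01), drop s2 (r2 .9); take s3 (r2 to s1 is
  # .04 <= .05), drop s4 (.8); take s5 (its only high-r2 partner s2 is gone);
  # drop s6 (r2 .2 to s5). Retained: s1, s3, s5.
  pair <- make_pair(paste0("s", 1:6), p_a = (1:6) / 100, p_b = rep(0.5, 6))
  r2 <- data.frame(snp_a = c("s1", "s1", "s3", "s2", "s5"),
                   snp_b = c("s2", "s3", "s4", "s5", "s6"),
                   r2 = c(0.9, 0.04, 0.8, 0.9, 0.2))
  pruned <- ld_prune(pair, r2_table = r2)
  expect_equal(pruned$snp_id, c("s1", "s3", "s5"))
})

test_that("pruning properties hold on random LD-structured instances", {
  for (s in 1:20) {
    panel <- small_panel(seed = 400 + s, n_blocks = 2, snps_per_block = 25,
                         rho = stats::runif(1, 0, 0.95), n_ind = 40)
    set.seed(500 + s)
    pair <- make_pair(panel$map$snp_id, p_a = stats::runif(50),
                      p_b = stats::runif(50), chrom = panel$map$chrom,
                      pos = panel$map$pos)
    pruned <- ld_prune(pair, panel = panel, r2_threshold = 0.05)
    r2m <- full_r2_matrix(panel)
    # matches a literal re-execution of the stated rule
    expect_equal(pruned$snp_id,
                 prune_oracle(pair$snp_id, pair$p_a, pair$chrom, pair$pos,
                              r2m[pair$snp_id, pair$snp_id], 0.05))
    # no retained pair exceeds the threshold; the global minimum-p survives
    kept <- r2m[pruned$snp_id, pruned$snp_id]
    expect_true(all(kept[upper.tri(kept)] <= 0.05))
    expect_true(pair$snp_id[which.min(pair$p_a)] %in% pruned$snp_id)
    # invariance to input row order
    shuf <- pair[sample(nrow(pair)), ]
    attributes(shuf)[c("drops", "class")] <- attributes(pair)[c("drops", "class")]
    expect_equal(ld_prune(shuf, panel = panel, r2_threshold = 0.05)$snp_id,
                 pruned$snp_id)
  }
})

test_that("pair SNPs absent from the LD panel are dropped or fatal as configured", {
  panel <- small_panel(seed = 42, n_blocks = 1, snps_per_block = 5, n_ind = 30)
  pair <- make_pair(c(panel$map$snp_id, "rs_unknown"),
                    p_a = runif(6), p_b = runif(6))
  expect_warning(pruned <- ld_prune(pair, panel = panel), "missing")
  expect_false("rs_unknown" %in% pruned$snp_id)
  expect_error(ld_prune(pair, panel = panel, missing_snp = "error"), "missing")
})

# --- Fisher exact test ----------------------------------------------------

test_that("balanced and degenerate tables give the expected exact p", {
  expect_equal(fisher_two_sided(5, 5, 5, 5)$p, 1)
  # full hypergeometric enumeration cross-check for the extreme table
  expect_equal(fisher_two_sided(10, 0, 0, 10)$p,
               stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-12)
  ft <- fisher_two_sided(10, 0, 0, 10)
  expect_false(ft$or_defined)  # sample OR has zero cells
  expect_equal(fisher_two_sided(3, 2, 4, 6)$or, (3 * 6) / (2 * 4))
})

test_that("fisher_two_sided matches fisher.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    cells <- as.integer(stats::rmultinom(1, sample(1:60, 1), rep(0.25, 4)))
    mine <- fisher_two_sided(cells[1], cells[2], cells[3], cells[4])$p
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

# --- Benjamini-Hochberg ---------------------------------------------------

test_that("BH adjustment reproduces hand-applied step-up values", {
  expect_equal(bh_adjust(0.04), 0.04)
  # hand rule: p_(i) * n / i = (.05,.05,.05,.05,.05); cumulative min = all .05
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH output is monotone, >= raw, <= 1, and order-preserving", {
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_false(is.unsorted(adj[order(p)]))
  }
})

# --- exact binomial -------------------------------------------------------

test_that("two-tailed binomial test matches enumeration and its known values", {
  # full enumeration: 2 * 2517 / 65536
  expect_equal(binomial_two_tailed(12, 16, 0.5), 2 * 2517 / 65536,
               tolerance = 1e-12)
  expect_equal(binomial_two_tailed(8, 16, 0.5), 1)
  expect_equal(binomial_two_tailed(0, 1, 0.5), 1)
  # all-concordant tail: 2 * (1/2)^10
  expect_equal(binomial_two_tailed(10, 10, 0.5), 2 * (1 / 2)^10,
               tolerance = 1e-12)
})

test_that("binomial test is symmetric at p0 = 0.5 and matches the oracle", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_two_tailed(k, n, 0.5),
                 binomial_two_tailed(n - k, n, 0.5), tolerance = 1e-12)
    p0 <- stats::runif(1, 0.05, 0.95)
    expect_equal(binomial_two_tailed(k, n, p0), binom_oracle(k, n, p0),
                 tolerance = 1e-12)
  }
})

# --- overlap scan ---------------------------------------------------------

test_that("cutoff 1 puts every SNP below in both traits, p = 1", {
  pair <- make_pair(paste0("s", 1:8), p_a = runif(8), p_b = runif(8))
  pruned <- ld_prune(pair, r2_table = data.frame(snp_a = character(0),
                                                 snp_b = character(0),
                                                 r2 = numeric(0)))
  suppressMessages(sc <- overlap_scan(pair, pruned, cutoffs = 1))
  expect_equal(unlist(sc[, c("n10", "n01", "n00")]), c(n10 = 0L, n01 = 0L, n00 = 0L))
  expect_equal(sc$n11, 8L)
  expect_equal(sc$fisher_p, 1)
})

test_that("a strong shared architecture is flagged at the smallest cutoffs", {
  panel <- small_panel(seed = 31, n_blocks = 20, snps_per_block = 20)
  f <- 0.3
  arch <- architecture(panel, shared_loci = data.frame(
    block = c(4, 9, 14), beta_a = beta_for_ncp(7, f, 19981, 56667),
    beta_b = beta_for_ncp(7, f, 21076, 63014)))
  ss <- simulate_sumstats_pair(panel, arch, seed = 32)
  pair <- align_alleles(ss$a, ss$b)
  pruned <- ld_prune(pair, panel = panel)
  suppressMessages(sc <- overlap_scan(pair, pruned, cutoffs = 10^-(2:6)))
  expect_true(any(sc$flag[sc$cutoff <= 1e-4]))
})

# --- permutation null -----------------------------------------------------

test_that("the add-one permutation estimator respects its bounds", {
  pair <- make_pair(paste0("s", 1:30), p_a = runif(30), p_b = runif(30))
  pruned <- ld_prune(pair, r2_table = data.frame(snp_a = character(0),
                                                 snp_b = character(0),
                                                 r2 = numeric(0)))
  expect_error(permute_overlap(pair, pruned, n_perm = 0, seed = 1))
  pm <- permute_overlap(pair, pruned, cutoffs = c(0.1, 0.01), n_perm = 1,
                        seed = 2)
  expect_true(all(pm$perm_p %in% c(0.5, 1)))
  pm2 <- permute_overlap(pair, pruned, cutoffs = c(0.1, 0.01), n_perm = 200,
                         seed = 3)
  expect_true(all(pm2$perm_p >= 1 / 201))  # never zero
})

test_that("permutation p agrees with a direct re-randomization estimate", {
  set.seed(44)
  pair <- make_pair(paste0("s", 1:60),
                    p_a = c(runif(6, 0, 0.01), runif(54)),
                    p_b = c(runif(6, 0, 0.01), runif(54)))
  pruned <- ld_prune(pair, r2_table = data.frame(snp_a = character(0),
                                                 snp_b = character(0),
                                                 r2 = numeric(0)))
  pm <- permute_overlap(pair, pruned, cutoffs = 0.01, n_perm = 2000, seed = 5)
  # independent oracle: the permutation null of n11 at fixed margins is
  # hypergeometric, so the null Fisher-p distribution can be enumerated
  idx <- match(pruned$snp_id, pair$snp_id)
  a <- pair$p_a[idx] <= 0.01
  b <- pair$p_b[idx] <= 0.01
  m <- length(idx)
  support <- max(0, sum(a) + sum(b) - m):min(sum(a), sum(b))
  null_p <- vapply(support, function(x) {
    fisher_two_sided(x, sum(a) - x, sum(b) - x, m - sum(a) - sum(b) + x)$p
  }, 0)
  wt <- stats::dhyper(support, sum(b), m - sum(b), sum(a))
  exact <- sum(wt[null_p <= pm$fisher_p])
  expect_lt(abs(pm$perm_p - exact), 0.02)
})

# --- direction concordance ------------------------------------------------

test_that("concordance counting and its binomial test behave as enumerated", {
  pair <- make_pair(paste0("s", 1:10), p_a = rep(1e-4, 10), p_b = rep(1e-4, 10),
                    beta_a = rep(0.1, 10),
                    beta_b = c(rep(0.1, 5), rep(-0.1, 5)))
  pruned <- ld_prune(pair, r2_table = data.frame(snp_a = character(0),
                                                 snp_b = character(0),
                                                 r2 = numeric(0)))
  dc <- direction_concordance(pair, pruned, 1e-2)
  expect_equal(dc$concordant, 5L)
  expect_equal(dc$total, 10L)
  expect_equal(dc$p, 1)  # point of symmetry

  all_conc <- make_pair(paste0("s", 1:10), p_a = rep(1e-4, 10),
                        p_b = rep(1e-4, 10))
  dc2 <- direction_concordance(all_conc, pruned, 1e-2)
  expect_equal(dc2$p, 2 * (1 / 2)^10, tolerance = 1e-12)

  # zero qualifying SNPs: flagged undefined, not 0/0
  dc3 <- direction_concordance(pair, pruned, 1e-10)
  expect_false(dc3$defined)
  expect_true(is.na(dc3$p))
})

test_that("an opposite-direction architecture yields sub-0.5 concordance", {
  panel <- small_panel(seed = 61, n_blocks = 12, snps_per_block = 15)
  f <- 0.3
  arch <- architecture(panel, shared_loci = data.frame(
    block = c(2, 5, 8, 11),
    beta_a = beta_for_ncp(6, f, 19981, 56667),
    beta_b = -beta_for_ncp(6, f, 21076, 63014)))
  frac <- vapply(1:8, function(s) {
    ss <- simulate_sumstats_pair(panel, arch, seed = 700 + s)
    pair <- align_alleles(ss$a, ss$b)
    pruned <- ld_prune(pair, panel = panel)
    dc <- direction_concordance(pair, pruned, 1e-2)
    if (dc$defined) dc$concordant / dc$total else NA_real_
  }, 0)
  expect_lt(mean(frac, na.rm = TRUE), 0.5)
})
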