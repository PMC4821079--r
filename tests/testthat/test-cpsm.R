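make_profiles <- function(za, zb, chrom = rep(1L, length(za)),
                          pos = seq_along(za) * 1000,
                          snp_id = sprintf("s%03d", seq_along(za))) {
  structure(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                       za = za, zb = zb, stringsAsFactors = FALSE),
            class = c("cpsm_profiles", "data.frame"))
}

# --- profile transformation ----------------------------------------------

test_that("uniform p-values transform to approximately standard normal", {
  set.seed(5)
  pair <- make_pair(sprintf("s%04d", 1:2000), p_a = runif(2000),
                    p_b = runif(2000))
  prof <- transform_profiles(pair)
  expect_equal(mean(prof$za), 0, tolerance = 0.01)
  expect_equal(stats::sd(prof$za), 1, tolerance = 0.05)
})

test_that("all-tied p-values give constant profiles and zero covariance", {
  pair <- make_pair(paste0("s", 1:20), p_a = rep(1, 20), p_b = runif(20))
  prof <- transform_profiles(pair)
  expect_equal(length(unique(prof$za)), 1L)
  w <- scan_windows(prof, window_size = 20, step = 20, min_snps = 2)
  expect_equal(w$stat, 0)
})

test_that("profiles are invariant to monotone transforms of p", {
  set.seed(6)
  p <- runif(50)
  pair1 <- make_pair(paste0("s", 1:50), p_a = p, p_b = runif(50))
  pair2 <- pair1
  pair2$p_a <- p^2  # strictly monotone
  attributes(pair2)[c("drops", "class")] <- attributes(pair1)[c("drops", "class")]
  expect_equal(transform_profiles(pair1)$za, transform_profiles(pair2)$za)
})

test_that("p-value underflow is clamped at the configurable floor", {
  pair <- make_pair(c("s1", "s2", "s3"), p_a = c(1e-40, 1e-35, 0.5),
                    p_b = rep(0.5, 3))
  expect_message(prof <- transform_profiles(pair, p_floor = 1e-30), "clamped")
  # both clamped values tie at the floor, hence share a rank
  expect_equal(prof$za[1], prof$za[2])
})

# --- window scan ----------------------------------------------------------

test_that("window covariance equals the hand-computed sample covariance", {
  za <- c(0.5, -1.2, 0.3, 2.1, -0.7, 1.4, 0.0, -0.3, 0.9, -1.8)
  zb <- c(1.1, -0.4, 0.8, 1.9, -1.0, 0.6, 0.2, -0.9, 1.3, -0.2)
  prof <- make_profiles(za, zb)
  w <- scan_windows(prof, window_size = 10, step = 10, min_snps = 2)
  expect_equal(nrow(w), 1L)
  expect_equal(w$stat, stats::cov(za, zb), tolerance = 1e-12)
})

test_that("identical profiles give the within-window variance", {
  set.seed(8)
  z <- rnorm(30)
  w <- scan_windows(make_profiles(z, z), window_size = 30, step = 30,
                    min_snps = 2)
  expect_equal(w$stat, stats::var(z), tolerance = 1e-12)
  expect_gt(w$stat, 0)
})

test_that("windows never span chromosomes and short chromosomes are skipped", {
  set.seed(9)
  prof <- make_profiles(rnorm(25), rnorm(25),
                        chrom = c(rep(1L, 20), rep(2L, 5)))
  expect_message(w <- scan_windows(prof, window_size = 10, step = 5,
                                   min_snps = 10), "skipped")
  expect_true(all(w$chrom == 1L))
  # trailing sub-min windows are not emitted
  expect_true(all(w$n_snps >= 10))
})

test_that("the window statistic is symmetric in the two traits", {
  set.seed(10)
  pair <- make_pair(sprintf("s%03d", 1:200), p_a = runif(200)^2,
                    p_b = runif(200))
  swapped <- pair
  swapped[, c("p_a", "p_b")] <- pair[, c("p_b", "p_a")]
  swapped[, c("beta_a", "beta_b")] <- pair[, c("beta_b", "beta_a")]
  attributes(swapped)[c("drops", "class")] <- attributes(pair)[c("drops", "class")]
  w1 <- scan_windows(transform_profiles(pair), 50, 25, 10)
  w2 <- scan_windows(transform_profiles(swapped), 50, 25, 10)
  expect_equal(w1$stat, w2$stat, tolerance = 1e-12)
})

test_that("independent null profiles have near-zero mean window statistic", {
  set.seed(11)
  stats <- unlist(lapply(1:10, function(i) {
    prof <- make_profiles(rnorm(500), rnorm(500))
    scan_windows(prof, 100, 50, 10)$stat
  }))
  expect_equal(mean(stats), 0, tolerance = 0.02)
})

# --- permutation threshold ------------------------------------------------

test_that("the median of the rotation null sits near zero", {
  set.seed(12)
  pair <- make_pair(sprintf("s%04d", 1:1000), p_a = runif(1000),
                    p_b = runif(1000))
  prof <- transform_profiles(pair)
  thr50 <- permutation_threshold(prof, 100, 50, 10, n_perm = 100,
                                 percentile = 0.5, seed = 13)
  expect_equal(thr50, 0, tolerance = 0.02)
  # n_perm = 1: threshold is an order statistic of a single rotation's windows
  thr1 <- permutation_threshold(prof, 100, 50, 10, n_perm = 1,
                                percentile = 0.9995, seed = 14)
  expect_true(is.finite(thr1))
})

test_that("rotation and shuffle modes are both deterministic given a seed", {
  set.seed(15)
  pair <- make_pair(sprintf("s%03d", 1:300), p_a = runif(300), p_b = runif(300))
  prof <- transform_profiles(pair)
  for (mode in c("rotate", "shuffle")) {
    t1 <- permutation_threshold(prof, 50, 25, 10, n_perm = 50, seed = 16,
                                mode = mode)
    t2 <- permutation_threshold(prof, 50, 25, 10, n_perm = 50, seed = 16,
                                mode = mode)
    expect_identical(t1, t2)
  }
})

# --- region calling -------------------------------------------------------

test_that("windows within the merge gap coalesce into one disjoint region", {
  # two significant windows 10 kb apart (< merge gap) and one far window
  w <- data.frame(chrom = c(1L, 1L, 1L), window = 1:3,
                  start_idx = c(1L, 5L, 20L), end_idx = c(4L, 9L, 24L),
                  start_pos = c(1000, 21000, 500000),
                  end_pos = c(11000, 31000, 510000),
                  start_snp = "x", end_snp = "y", n_snps = 5L,
                  stat = c(0.5, 0.6, 0.7))
  pair <- make_pair(sprintf("s%02d", 1:30), p_a = runif(30, 0.1, 1),
                    p_b = runif(30, 0.1, 1),
                    pos = seq(1000, 510000, length.out = 30))
  reg <- call_regions(w, pair, threshold = 0.4, merge_gap = 50000)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_windows, c(2L, 1L))
  expect_equal(reg$peak_stat, c(0.6, 0.7))
  # disjoint after merging
  expect_true(all(reg$start[-1] > reg$end[-nrow(reg)] + 50000))
  # lead SNPs fall inside their region
  lead_pos <- pair$pos[match(reg$lead_snp_a, pair$snp_id)]
  expect_true(all(lead_pos >= reg$start & lead_pos <= reg$end))

  none <- call_regions(w, pair, threshold = 1)
  expect_equal(nrow(none), 0L)
})

test_that("a planted shared locus is recovered with correct direction", {
  panel <- small_panel(seed = 17, n_blocks = 10, snps_per_block = 50,
                       rho = 0.8, n_ind = 150)
  f <- 0.3
  arch <- architecture(panel, shared_loci = data.frame(
    block = 6, beta_a = beta_for_ncp(8, f, 19981, 56667),
    beta_b = -beta_for_ncp(8, f, 21076, 63014)))
  ss <- simulate_sumstats_pair(panel, arch, seed = 18)
  pair <- align_alleles(ss$a, ss$b)
  prof <- transform_profiles(pair)
  w <- scan_windows(prof)
  thr <- permutation_threshold(prof, n_perm = 300, seed = 19)
  reg <- call_regions(w, pair, thr)
  causal_pos <- panel$map$pos[match(arch$shared$snp_id, panel$map$snp_id)]
  hit <- reg$start <= causal_pos & reg$end >= causal_pos
  expect_true(any(hit))
  expect_false(reg$direction_agreement[which(hit)[1]])
  expect_true(all(reg$peak_stat > thr))
})

# --- subtype annotation ---------------------------------------------------

test_that("subtype annotation counts lower-p leads by brute-force recount", {
  set.seed(20)
  ids <- sprintf("s%02d", 1:12)
  pair <- make_pair(ids, p_a = runif(12), p_b = runif(12))
  reg <- structure(data.frame(chrom = 1L, start = 1, end = 1e6,
                              n_windows = 1L, peak_stat = 1,
                              lead_snp_a = ids, p_a = pair$p_a, beta_a = 0.1,
                              lead_snp_b = ids, p_b = pair$p_b, beta_b = 0.1,
                              direction_agreement = TRUE,
                              stringsAsFactors = FALSE),
                   threshold = 0.5, class = c("cpsm_regions", "data.frame"))
  p1 <- runif(12)
  p2 <- runif(12)
  sub1 <- make_sumstats(ids, p = p1, beta = rnorm(12))
  sub2 <- make_sumstats(ids, p = p2, beta = rnorm(12))
  ann <- annotate_subtypes(reg, pair, sub1, sub2)
  expect_equal(ann$summary$n_lower_sub1, sum(p1 < p2))
  expect_equal(ann$summary$n_tested, 12L)
  expect_equal(ann$summary$binomial_p,
               binom_oracle(sum(p1 < p2), 12, 0.5), tolerance = 1e-12)

  # identical subtype tables: every tie counts as "not lower"
  ann_tie <- annotate_subtypes(reg, pair, sub1, sub1)
  expect_equal(ann_tie$summary$n_lower_sub1, 0L)
  expect_equal(ann_tie$summary$n_same_sign, 12L)

  # a lead missing from one subtype table is excluded and noted
  sub2_miss <- make_sumstats(ids[-1], p = p2[-1], beta = rnorm(11),
                             pos = (2:12) * 1000)
  expect_message(ann_miss <- annotate_subtypes(reg, pair, sub1, sub2_miss),
                 "absent")
  expect_equal(ann_miss$summary$n_tested, 11L)
  expect_equal(ann_miss$summary$n_missing, 1L)
})

test_that("subtype effects are aligned to the pair orientation before sign checks", {
  ids <- c("s1", "s2")
  pair <- make_pair(ids, p_a = c(0.01, 0.02), p_b = c(0.01, 0.02),
                    effect_allele = c("A", "A"), other_allele = c("G", "G"))
  reg <- structure(data.frame(chrom = 1L, start = 1, end = 1e6, n_windows = 1L,
                              peak_stat = 1, lead_snp_a = ids, p_a = pair$p_a,
                              beta_a = 0.1, lead_snp_b = ids, p_b = pair$p_b,
                              beta_b = 0.1, direction_agreement = TRUE,
                              stringsAsFactors = FALSE),
                   threshold = 0.5, class = c("cpsm_regions", "data.frame"))
  # sub1 reports s2 with swapped alleles and negated beta: same direction
  sub1 <- make_sumstats(ids, p = c(0.1, 0.1), beta = c(0.2, -0.2),
                        effect_allele = c("A", "G"), other_allele = c("G", "A"))
  sub2 <- make_sumstats(ids, p = c(0.2, 0.2), beta = c(0.2, 0.2))
  ann <- annotate_subtypes(reg, pair, sub1, sub2)
  expect_equal(ann$regions$sub1_beta, c(0.2, 0.2))
  expect_equal(ann$summary$n_same_sign, 2L)
})
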