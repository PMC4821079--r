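# Shared fixture builders and independent oracles. Everything is generated in
# code; no stored data files.

# Construct a harmonized pair directly (bypassing align_alleles) for tests of
# downstream stages.
make_pair <- function(snp_id, p_a, p_b, chrom = rep(1L, length(snp_id)),
                      pos = seq_along(snp_id) * 1000,
                      beta_a = rep(0.1, length(snp_id)), beta_b = beta_a,
                      effect_allele = rep("A", length(snp_id)),
                      other_allele = rep("G", length(snp_id))) {
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = effect_allele, other_allele = other_allele,
                   beta_a = beta_a, se_a = 0.05, p_a = p_a,
                   beta_b = beta_b, se_b = 0.05, p_b = p_b,
                   flipped = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  structure(df, drops = c(non_overlap = 0L, discordant_position = 0L,
                          palindromic = 0L, allele_mismatch = 0L),
            class = c("harmonized_pair", "data.frame"))
}

make_sumstats <- function(snp_id, p, beta = rep(0.1, length(snp_id)),
                          chrom = rep(1L, length(snp_id)),
                          pos = seq_along(snp_id) * 1000,
                          effect_allele = rep("A", length(snp_id)),
                          other_allele = rep("G", length(snp_id)),
                          se = rep(0.05, length(snp_id))) {
  as_sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         effect_allele = effect_allele,
                         other_allele = other_allele,
                         beta = beta, se = se, p = p,
                         stringsAsFactors = FALSE))
}

# Literal re-execution of the stated pruning rule on a full r2 matrix:
# sort by p (ties by chrom, pos), take the top, remove everything remaining
# with r2 > threshold to it, repeat.
prune_oracle <- function(ids, p, chrom, pos, r2mat, thr) {
  remaining <- order(p, chrom, pos)
  kept <- integer(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    remaining <- remaining[-1]
    if (length(remaining)) {
      remaining <- remaining[r2mat[top, remaining] <= thr]
    }
  }
  ids[kept]
}

# Full block-diagonal r2 matrix of a panel (cross-block zero by construction).
full_r2_matrix <- function(panel) {
  m <- nrow(panel$map)
  r2 <- matrix(0, m, m, dimnames = list(panel$map$snp_id, panel$map$snp_id))
  for (idx in split(seq_len(m), panel$map$block)) {
    r <- suppressWarnings(stats::cor(panel$dosage[, idx, drop = FALSE]))
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    r2[idx, idx] <- r^2
  }
  r2
}

# Long-format r2 table (upper triangle) from a full matrix.
r2_long <- function(r2mat) {
  ut <- which(upper.tri(r2mat), arr.ind = TRUE)
  data.frame(snp_a = rownames(r2mat)[ut[, 1]],
             snp_b = colnames(r2mat)[ut[, 2]],
             r2 = r2mat[ut], stringsAsFactors = FALSE)
}

# Independent enumeration oracle for the exact two-tailed binomial test:
# sum of probabilities of all outcomes no more likely than the observed one.
binom_oracle <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# Small LD-structured panel for module tests.
small_panel <- function(seed = 1, n_blocks = 10, snps_per_block = 20,
                        rho = 0.8, n_ind = 150, maf = c(0.1, 0.5),
                        n_chrom = 1) {
  simulate_panel(ld_block_spec(n_blocks, snps_per_block, rho, maf, n_chrom),
                 n_ind, seed = seed)
}
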