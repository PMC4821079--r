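# Overlap of association signals between two traits: greedy LD pruning,
# cutoff-stratified 2x2 Fisher exact enrichment with FDR correction, a
# permutation null, and effect-direction concordance.

#' Greedy p-value-ordered LD pruning
#'
#' Sorts the harmonized SNPs by association p-value in the ordering trait and
#' repeatedly takes the best remaining SNP, removing every remaining SNP with
#' r2 above the threshold to it, until no SNP remains. The retained set is in
#' approximate linkage equilibrium. Ties in p are broken by `(chrom, pos)` so
#' the output is deterministic and invariant to input row order.
#'
#' @param pair A `harmonized_pair`.
#' @param panel A `ref_panel` providing pairwise r2 (block-diagonal; r2
#'   across blocks is zero). Alternatively supply `r2_table`.
#' @param r2_table Data frame `snp_a`, `snp_b`, `r2` of pairwise r2 values;
#'   unlisted pairs are treated as r2 = 0.
#' @param r2_threshold Removal threshold (default 0.05): SNPs with r2 strictly
#'   greater than this to a retained SNP are removed.
#' @param order_by Which trait's p-values order the greedy pass (`"a"` or
#'   `"b"`).
#' @param missing_snp With a `panel` source, what to do with pair SNPs absent
#'   from the panel: `"drop"` them with a warning (default) or raise an
#'   `"error"`.
#' @return A `pruned_set`: data frame `snp_id`, `p` (ordering trait) in
#'   selection order, with attributes `r2_threshold`, `order_by`,
#'   `n_missing_ld`.
#' @export
ld_prune <- function(pair, panel = NULL, r2_table = NULL, r2_threshold = 0.05,
                     order_by = c("a", "b"), missing_snp = c("drop", "error")) {
  stopifnot(inherits(pair, "harmonized_pair"),
            r2_threshold >= 0, r2_threshold <= 1)
  order_by <- match.arg(order_by)
  missing_snp <- match.arg(missing_snp)
  if (is.null(panel) == is.null(r2_table)) {
    stop("supply exactly one LD source: panel or r2_table")
  }
  p <- if (order_by == "a") pair$p_a else pair$p_b
  ids <- pair$snp_id
  n <- length(ids)
  n_missing <- 0L

  neighbors <- vector("list", n)  # indices with r2 > threshold, per SNP
  if (!is.null(panel)) {
    loc <- match(ids, panel$map$snp_id)
    miss <- is.na(loc)
    if (any(miss)) {
      if (missing_snp == "error") {
        stop(sum(miss), " pair SNP(s) missing from the LD panel")
      }
      warning(sum(miss), " SNP(s) missing from the LD panel dropped before pruning")
      n_missing <- sum(miss)
    }
    keep_idx <- which(!miss)
    blk <- panel$map$block[loc[keep_idx]]
    for (bidx in split(seq_along(keep_idx), blk)) {
      if (length(bidx) < 2) next
      cols <- loc[keep_idx[bidx]]
      r2 <- suppressWarnings(stats::cor(panel$dosage[, cols, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 1
      for (j in seq_along(bidx)) {
        nb <- bidx[which(r2[j, ] > r2_threshold)]
        neighbors[[keep_idx[bidx[j]]]] <- keep_idx[setdiff(nb, bidx[j])]
      }
    }
    alive0 <- !miss
  } else {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(r2_table)))
    ia <- match(r2_table$snp_a, ids)
    ib <- match(r2_table$snp_b, ids)
    sel <- !is.na(ia) & !is.na(ib) & r2_table$r2 > r2_threshold & ia != ib
    for (k in which(sel)) {
      neighbors[[ia[k]]] <- c(neighbors[[ia[k]]], ib[k])
      neighbors[[ib[k]]] <- c(neighbors[[ib[k]]], ia[k])
    }
    alive0 <- rep(TRUE, n)
  }

  ord <- order(p, pair$chrom, pair$pos)
  alive <- alive0
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    nb <- neighbors[[i]]
    if (length(nb)) alive[nb] <- FALSE
  }
  structure(data.frame(snp_id = ids[kept], p = p[kept],
                       stringsAsFactors = FALSE),
            r2_threshold = r2_threshold, order_by = order_by,
            n_missing_ld = n_missing,
            class = c("pruned_set", "data.frame"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null at fixed margins:
#' the sum of probabilities of all tables whose probability does not exceed
#' that of the observed table (the convention of R's exact tests, with the
#' same 1e-7 relative tolerance for floating-point ties). The odds ratio is
#' the sample odds ratio `(n11 * n00) / (n10 * n01)`.
#'
#' @param n11,n10,n01,n00 Non-negative cell counts (total >= 1). `n11` counts
#'   units positive in both classifications; `n10`/`n01` positive in the
#'   first/second only.
#' @return List with `p`, `or`, and `or_defined` (`FALSE` when a zero cell
#'   makes the sample odds ratio infinite or undefined).
#' @export
fisher_two_sided <- function(n11, n10, n01, n00) {
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  N <- n11 + n10 + n01 + n00
  stopifnot(N >= 1)
  r1 <- n11 + n10   # margin: positive in classification 1
  c1 <- n11 + n01   # margin: positive in classification 2
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  d <- stats::dhyper(lo:hi, c1, N - c1, r1)
  p <- min(1, sum(d[d <= d[n11 - lo + 1] * (1 + 1e-7)]))
  or <- (n11 * n00) / (n10 * n01)
  list(p = p, or = or, or_defined = is.finite(or) && !is.nan(or))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), order-preserving with
#' respect to the input positions.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order (empty in, empty out).
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Exact two-tailed binomial test
#'
#' Exact two-tailed p-value for `k` successes in `n` trials against null
#' proportion `p0`: the sum of probabilities of all outcomes no more likely
#' than the observed one (the minimum-likelihood convention of
#' [stats::binom.test()], which this wraps), capped at 1.
#'
#' @param k Successes (0..n).
#' @param n Trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @return P-value.
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

# counts of pruned SNPs below/above a cutoff in each trait
overlap_counts <- function(pa, pb, cutoff) {
  a <- pa <= cutoff
  b <- pb <= cutoff
  c(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b), n00 = sum(!a & !b))
}

#' Cutoff-stratified overlap scan with Fisher exact tests and FDR correction
#'
#' For each p-value cutoff, counts the LD-pruned SNPs below/above the cutoff
#' in each trait (one 2x2 table per cutoff), tests each table with the
#' two-sided Fisher exact test, adjusts the whole scan with
#' Benjamini-Hochberg, and flags cutoffs with corrected p below `flag_alpha`
#' as showing an excess of overlapping signals.
#'
#' @param pair A `harmonized_pair`.
#' @param pruned A `pruned_set` from [ld_prune()].
#' @param cutoffs P-value cutoffs (default `1e-2` to `1e-6`); sorted
#'   decreasing internally.
#' @param flag_alpha Corrected-p significance level for the excess-overlap
#'   flag (default 0.01).
#' @return Data frame, one row per cutoff: `cutoff`, `n11`, `n10`, `n01`,
#'   `n00`, `fisher_or`, `or_defined`, `fisher_p`, `fdr_p`, `flag`.
#' @export
overlap_scan <- function(pair, pruned, cutoffs = 10^-(2:6), flag_alpha = 0.01) {
  stopifnot(inherits(pair, "harmonized_pair"), inherits(pruned, "pruned_set"))
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  idx <- match(pruned$snp_id, pair$snp_id)
  pa <- pair$p_a[idx]
  pb <- pair$p_b[idx]
  rows <- lapply(cutoffs, function(cf) {
    ct <- overlap_counts(pa, pb, cf)
    if (ct["n11"] + ct["n10"] == 0L || ct["n11"] + ct["n01"] == 0L) {
      message("cutoff ", format(cf), ": empty 'below' margin; Fisher p = 1")
    }
    ft <- fisher_two_sided(ct["n11"], ct["n10"], ct["n01"], ct["n00"])
    data.frame(cutoff = cf, n11 = ct[["n11"]], n10 = ct[["n10"]],
               n01 = ct[["n01"]], n00 = ct[["n00"]],
               fisher_or = ft$or, or_defined = ft$or_defined,
               fisher_p = ft$p)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bh_adjust(out$fisher_p)
  out$flag <- out$fdr_p < flag_alpha
  rownames(out) <- NULL
  out
}

#' Permutation null for the overlap scan
#'
#' In each permutation cycle the assignment of p-values to SNPs is shuffled
#' independently within each trait's LD-pruned vector, and the Fisher p for
#' overlap is recomputed at every cutoff. The empirical p-value per cutoff is
#' the add-one estimator `(1 + #\{null p <= observed p\}) / (n_perm + 1)`,
#' which can never return 0.
#'
#' @param pair A `harmonized_pair`.
#' @param pruned A `pruned_set`.
#' @param cutoffs P-value cutoffs.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Data frame `cutoff`, `fisher_p` (observed), `perm_p`.
#' @export
permute_overlap <- function(pair, pruned, cutoffs = 10^-(2:6), n_perm, seed) {
  stopifnot(n_perm >= 1)
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  idx <- match(pruned$snp_id, pair$snp_id)
  pa <- pair$p_a[idx]
  pb <- pair$p_b[idx]
  m <- length(pa)
  k <- length(cutoffs)

  # margins are invariant under within-trait shuffling: only n11 varies, so
  # precompute the Fisher p as a function of n11 for each cutoff
  obs_p <- numeric(k)
  lut <- vector("list", k)
  lo <- integer(k)
  for (j in seq_len(k)) {
    ct <- overlap_counts(pa, pb, cutoffs[j])
    mA <- ct["n11"] + ct["n10"]
    mB <- ct["n11"] + ct["n01"]
    lo[j] <- max(0L, mA + mB - m)
    hi <- min(mA, mB)
    lut[[j]] <- vapply(lo[j]:hi, function(x) {
      fisher_two_sided(x, mA - x, mB - x, m - mA - mB + x)$p
    }, 0)
    obs_p[j] <- lut[[j]][ct["n11"] - lo[j] + 1L]
  }

  set.seed(seed)
  below_a <- outer(pa, cutoffs, `<=`)
  below_b <- outer(pb, cutoffs, `<=`)
  hits <- integer(k)
  for (r in seq_len(n_perm)) {
    sa <- below_a[sample.int(m), , drop = FALSE]
    sb <- below_b[sample.int(m), , drop = FALSE]
    n11 <- colSums(sa & sb)
    for (j in seq_len(k)) {
      if (lut[[j]][n11[j] - lo[j] + 1L] <= obs_p[j]) hits[j] <- hits[j] + 1L
    }
  }
  data.frame(cutoff = cutoffs, fisher_p = obs_p,
             perm_p = (1 + hits) / (n_perm + 1))
}

#' Effect-direction concordance among doubly-significant SNPs
#'
#' Among LD-pruned SNPs below the cutoff in both traits, counts those whose
#' harmonized effect signs agree, and tests the concordant fraction against
#' 0.5 with the exact two-tailed binomial test.
#'
#' @param pair A `harmonized_pair`.
#' @param pruned A `pruned_set`.
#' @param cutoff P-value cutoff applied to both traits.
#' @return List `concordant`, `total`, `p`, `defined` (`FALSE`, with `p = NA`,
#'   when no SNP qualifies).
#' @export
direction_concordance <- function(pair, pruned, cutoff) {
  idx <- match(pruned$snp_id, pair$snp_id)
  sel <- pair$p_a[idx] <= cutoff & pair$p_b[idx] <= cutoff
  total <- sum(sel)
  if (total == 0L) {
    return(list(concordant = 0L, total = 0L, p = NA_real_, defined = FALSE))
  }
  conc <- sum(sign(pair$beta_a[idx][sel]) == sign(pair$beta_b[idx][sel]))
  list(concordant = conc, total = total,
       p = binomial_two_tailed(conc, total, 0.5), defined = TRUE)
}
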