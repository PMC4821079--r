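# Cross-phenotype spatial mapping: rank-normalized association profiles,
# sliding-window cross-trait covariance, circular-rotation permutation null,
# region calling, and subtype annotation.

#' Transform a harmonized pair into rank-normalized association profiles
#'
#' Per trait, each SNP's p-value becomes `-log10(p)` and is then
#' rank-normalized within its chromosome (rank mapped to a normal quantile
#' via `qnorm(rank / (n + 1))`, ties averaged), making the downstream window
#' covariance robust to the two traits' different p-value distributions and
#' invariant to any strictly monotone transform of either trait's p-values.
#'
#' @param pair A `harmonized_pair`.
#' @param p_floor P-values below this floor are clamped to it before the log
#'   transform (default 1e-30); clamping is reported.
#' @return A `cpsm_profiles` data frame: `snp_id`, `chrom`, `pos`, `za`, `zb`.
#' @export
transform_profiles <- function(pair, p_floor = 1e-30) {
  stopifnot(inherits(pair, "harmonized_pair"), p_floor > 0)
  clamped <- sum(pair$p_a < p_floor) + sum(pair$p_b < p_floor)
  if (clamped > 0) {
    message(clamped, " p-value(s) clamped at the floor ", format(p_floor))
  }
  rank_norm <- function(p) {
    v <- -log10(pmax(p, p_floor))
    unsplit(lapply(split(v, pair$chrom), function(x) {
      stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
    }), pair$chrom)
  }
  structure(data.frame(snp_id = pair$snp_id, chrom = pair$chrom,
                       pos = pair$pos,
                       za = rank_norm(pair$p_a), zb = rank_norm(pair$p_b),
                       stringsAsFactors = FALSE),
            class = c("cpsm_profiles", "data.frame"))
}

# sample covariance of x and y over [starts[i], ends[i]] windows, via cumsums
window_cov <- function(x, y, starts, ends) {
  cx <- c(0, cumsum(x))
  cy <- c(0, cumsum(y))
  cxy <- c(0, cumsum(x * y))
  n <- ends - starts + 1
  sx <- cx[ends + 1] - cx[starts]
  sy <- cy[ends + 1] - cy[starts]
  sxy <- cxy[ends + 1] - cxy[starts]
  (sxy - sx * sy / n) / (n - 1)
}

# window start/end indices for one chromosome of n SNPs
window_index <- function(n, window_size, step, min_snps) {
  starts <- seq.int(1L, n, by = step)
  ends <- pmin(starts + window_size - 1L, n)
  keep <- (ends - starts + 1L) >= min_snps
  list(starts = starts[keep], ends = ends[keep])
}

#' Sliding-window cross-trait covariance scan
#'
#' Slides windows of `window_size` SNPs (advancing by `step`) along each
#' chromosome and computes, per window, the sample covariance of the two
#' traits' rank-normalized profiles. Windows never span chromosomes; a
#' trailing short window is kept only if it holds at least `min_snps` SNPs;
#' chromosomes with fewer than `min_snps` SNPs are skipped.
#'
#' @param profiles A `cpsm_profiles` from [transform_profiles()].
#' @param window_size Window size in SNPs (default 100).
#' @param step Step in SNPs (default 50).
#' @param min_snps Minimum SNPs per window (default 10; `2 <= min_snps <=
#'   window_size`).
#' @return Data frame of window statistics: `chrom`, `window`, `start_idx`,
#'   `end_idx`, `start_pos`, `end_pos`, `start_snp`, `end_snp`, `n_snps`,
#'   `stat`.
#' @export
scan_windows <- function(profiles, window_size = 100, step = 50, min_snps = 10) {
  stopifnot(inherits(profiles, "cpsm_profiles"),
            window_size >= min_snps, min_snps >= 2, step >= 1)
  out <- lapply(split(seq_len(nrow(profiles)), profiles$chrom), function(idx) {
    n <- length(idx)
    if (n < min_snps) {
      message("chromosome ", profiles$chrom[idx[1]], " has fewer than ",
              min_snps, " SNPs; skipped")
      return(NULL)
    }
    w <- window_index(n, window_size, step, min_snps)
    if (!length(w$starts)) return(NULL)
    stat <- window_cov(profiles$za[idx], profiles$zb[idx], w$starts, w$ends)
    data.frame(chrom = profiles$chrom[idx[1]],
               window = seq_along(w$starts),
               start_idx = idx[w$starts], end_idx = idx[w$ends],
               start_pos = profiles$pos[idx[w$starts]],
               end_pos = profiles$pos[idx[w$ends]],
               start_snp = profiles$snp_id[idx[w$starts]],
               end_snp = profiles$snp_id[idx[w$ends]],
               n_snps = w$ends - w$starts + 1L,
               stat = stat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no chromosome had enough SNPs to form a window")
  rownames(out) <- NULL
  out
}

#' Permutation threshold for the window scan
#'
#' In each permutation, trait B's profile is circularly rotated by a random
#' offset within each chromosome — preserving each trait's local
#' autocorrelation (from LD) while breaking the cross-trait alignment — and
#' all window statistics are recomputed. The threshold is the requested
#' percentile (default the 99.95th) of the pooled null statistics. A full
#' within-chromosome shuffle is available for comparison.
#'
#' @param profiles A `cpsm_profiles`.
#' @param window_size,step,min_snps As in [scan_windows()].
#' @param n_perm Number of permutations (>= 1; default 1000).
#' @param percentile Pooled-null percentile in `(0, 1)` (default 0.9995).
#' @param seed Integer seed.
#' @param mode `"rotate"` (default) or `"shuffle"`.
#' @return Threshold value (scalar).
#' @export
permutation_threshold <- function(profiles, window_size = 100, step = 50,
                                  min_snps = 10, n_perm = 1000,
                                  percentile = 0.9995, seed,
                                  mode = c("rotate", "shuffle")) {
  stopifnot(inherits(profiles, "cpsm_profiles"), n_perm >= 1,
            percentile > 0, percentile < 1)
  mode <- match.arg(mode)
  set.seed(seed)
  chrom_idx <- split(seq_len(nrow(profiles)), profiles$chrom)
  chrom_idx <- Filter(function(idx) length(idx) >= min_snps, chrom_idx)
  wins <- lapply(chrom_idx, function(idx) {
    window_index(length(idx), window_size, step, min_snps)
  })
  null_stats <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    per_chrom <- mapply(function(idx, w) {
      n <- length(idx)
      zb <- profiles$zb[idx]
      zb <- if (mode == "rotate") {
        off <- if (n > 1) sample.int(n - 1L, 1L) else 0L
        c(zb[(off + 1):n], zb[seq_len(off)])
      } else {
        zb[sample.int(n)]
      }
      window_cov(profiles$za[idx], zb, w$starts, w$ends)
    }, chrom_idx, wins, SIMPLIFY = FALSE)
    null_stats[[r]] <- unlist(per_chrom, use.names = FALSE)
  }
  unname(stats::quantile(unlist(null_stats, use.names = FALSE), percentile))
}

#' Call shared-association regions from significant windows
#'
#' Windows with statistic above the threshold are merged into regions when
#' they overlap or lie within `merge_gap` base pairs of each other on the
#' same chromosome. Each region reports its peak statistic and, per trait,
#' the lead SNP (smallest association p inside the region) with its p and
#' harmonized effect; `direction_agreement` records whether the two lead
#' effects share sign.
#'
#' @param windows Window statistics from [scan_windows()].
#' @param pair The `harmonized_pair` the scan was built from.
#' @param threshold Statistic threshold (from [permutation_threshold()] or
#'   user-supplied).
#' @param merge_gap Maximum gap in bp between merged windows (default 50000).
#' @return A `cpsm_regions` data frame (possibly 0 rows): `chrom`, `start`,
#'   `end` (bp, 1-based inclusive), `n_windows`, `peak_stat`, `lead_snp_a`,
#'   `p_a`, `beta_a`, `lead_snp_b`, `p_b`, `beta_b`, `direction_agreement`.
#' @export
call_regions <- function(windows, pair, threshold, merge_gap = 50000) {
  stopifnot(inherits(pair, "harmonized_pair"), is.finite(threshold))
  sig <- windows[windows$stat > threshold, , drop = FALSE]
  empty <- data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
                      n_windows = integer(0), peak_stat = numeric(0),
                      lead_snp_a = character(0), p_a = numeric(0),
                      beta_a = numeric(0), lead_snp_b = character(0),
                      p_b = numeric(0), beta_b = numeric(0),
                      direction_agreement = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) {
    return(structure(empty, threshold = threshold,
                     class = c("cpsm_regions", "data.frame")))
  }
  sig <- sig[order(sig$chrom, sig$start_pos), , drop = FALSE]
  regions <- list()
  cur <- sig[1, ]
  cur_n <- 1L
  flush <- function(cur, cur_n) {
    inside <- pair$chrom == cur$chrom & pair$pos >= cur$start_pos &
      pair$pos <= cur$end_pos
    la <- which(inside)[which.min(pair$p_a[inside])]
    lb <- which(inside)[which.min(pair$p_b[inside])]
    data.frame(chrom = cur$chrom, start = cur$start_pos, end = cur$end_pos,
               n_windows = cur_n, peak_stat = cur$stat,
               lead_snp_a = pair$snp_id[la], p_a = pair$p_a[la],
               beta_a = pair$beta_a[la],
               lead_snp_b = pair$snp_id[lb], p_b = pair$p_b[lb],
               beta_b = pair$beta_b[lb],
               direction_agreement = sign(pair$beta_a[la]) == sign(pair$beta_b[lb]),
               stringsAsFactors = FALSE)
  }
  if (nrow(sig) > 1) {
    for (i in 2:nrow(sig)) {
      w <- sig[i, ]
      if (w$chrom == cur$chrom && w$start_pos <= cur$end_pos + merge_gap) {
        cur$end_pos <- max(cur$end_pos, w$end_pos)
        cur$stat <- max(cur$stat, w$stat)
        cur_n <- cur_n + 1L
      } else {
        regions[[length(regions) + 1L]] <- flush(cur, cur_n)
        cur <- w
        cur_n <- 1L
      }
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur, cur_n)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("cpsm_regions", "data.frame"))
}

#' Annotate regions with subtype association at the trait-A lead SNP
#'
#' Looks up each region's trait-A lead SNP in two subtype summary-statistics
#' tables (e.g. the two clinical subtypes of trait A), aligning subtype
#' effects to the harmonized pair's allele orientation, and summarizes: how
#' many leads have a strictly lower p in the first subtype than in the second
#' (ties count as not lower), with an exact two-tailed binomial test against
#' 0.5, and how many leads have same-sign subtype effects.
#'
#' @param regions A `cpsm_regions` from [call_regions()].
#' @param pair The `harmonized_pair` (supplies lead-SNP allele orientation).
#' @param sub1,sub2 Subtype `sumstats` tables.
#' @return List: `regions` (input plus `sub1_p`, `sub1_beta`, `sub2_p`,
#'   `sub2_beta`, `subtype_same_sign`) and `summary` (list `n_lower_sub1`,
#'   `n_tested`, `binomial_p`, `n_same_sign`, `n_missing`).
#' @export
annotate_subtypes <- function(regions, pair, sub1, sub2) {
  stopifnot(inherits(regions, "cpsm_regions"),
            inherits(sub1, "sumstats"), inherits(sub2, "sumstats"))
  lookup <- function(sub, lead_ids) {
    i <- match(lead_ids, sub$snp_id)
    j <- match(lead_ids, pair$snp_id)
    beta <- sub$beta[i]
    # align subtype effect to the pair's orientation at the lead SNP
    same <- sub$effect_allele[i] == pair$effect_allele[j] |
      unname(DNA_COMPLEMENT[sub$effect_allele[i]]) == pair$effect_allele[j]
    swap <- sub$effect_allele[i] == pair$other_allele[j] |
      unname(DNA_COMPLEMENT[sub$effect_allele[i]]) == pair$other_allele[j]
    beta[!is.na(i) & !same & swap] <- -beta[!is.na(i) & !same & swap]
    beta[!is.na(i) & !same & !swap] <- NA  # irreconcilable alleles
    list(p = sub$p[i], beta = beta)
  }
  l1 <- lookup(sub1, regions$lead_snp_a)
  l2 <- lookup(sub2, regions$lead_snp_a)
  regions$sub1_p <- l1$p
  regions$sub1_beta <- l1$beta
  regions$sub2_p <- l2$p
  regions$sub2_beta <- l2$beta
  regions$subtype_same_sign <- sign(l1$beta) == sign(l2$beta)

  tested <- !is.na(l1$p) & !is.na(l2$p)
  n_missing <- sum(!tested)
  if (n_missing > 0) {
    message(n_missing, " lead SNP(s) absent from a subtype table; excluded")
  }
  n_lower <- sum(l1$p[tested] < l2$p[tested])
  n_tested <- sum(tested)
  bp <- if (n_tested > 0) binomial_two_tailed(n_lower, n_tested, 0.5) else NA_real_
  list(regions = regions,
       summary = list(n_lower_sub1 = n_lower, n_tested = n_tested,
                      binomial_p = bp,
                      n_same_sign = sum(regions$subtype_same_sign[tested],
                                        na.rm = TRUE),
                      n_missing = n_missing))
}

#' Write regions as a BED file
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions A `cpsm_regions`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = paste0("chr", regions$chrom),
                    start = as.integer(regions$start) - 1L,
                    end = as.integer(regions$end),
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = signif(regions$peak_stat, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
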