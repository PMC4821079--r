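# Allele harmonization: merge two summary-statistics tables so effect signs
# are directly comparable.

#' Merge two summary-statistics tables with allele alignment
#'
#' Inner-joins two validated `sumstats` tables on SNP id and aligns study B's
#' effects to study A's allele orientation. A record is aligned by at most one
#' effect/other allele swap and/or one strand complement:
#' \itemize{
#'   \item identical alleles: kept as is (`flipped = FALSE`);
#'   \item B's effect allele equals A's other allele (directly or after strand
#'     complement): `beta_b` is negated and `flipped = TRUE`;
#'   \item any other allele pair: dropped and counted as `allele_mismatch`.
#' }
#' Strand-ambiguous palindromic SNPs (A/T, C/G) cannot be resolved without
#' allele-frequency information and are dropped by default. Records whose
#' chromosome/position disagree between the studies are dropped, not
#' reconciled.
#'
#' @param a,b Validated `sumstats` objects (trait A and trait B).
#' @param drop_palindromic Drop A/T and C/G SNPs (default `TRUE`). If `FALSE`,
#'   palindromic SNPs are aligned assuming both studies report the same strand.
#' @return A `harmonized_pair` object: data frame with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele` (study A orientation),
#'   `beta_a`, `se_a`, `p_a`, `beta_b`, `se_b`, `p_b`, `flipped`; the `drops`
#'   attribute counts study-B records lost to `non_overlap`,
#'   `discordant_position`, `palindromic`, and `allele_mismatch`.
#' @export
align_alleles <- function(a, b, drop_palindromic = TRUE) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  ib <- match(a$snp_id, b$snp_id)
  sel <- !is.na(ib)
  non_overlap <- nrow(b) - sum(sel)
  ja <- a[sel, , drop = FALSE]
  jb <- b[ib[sel], , drop = FALSE]

  discordant <- ja$chrom != jb$chrom | ja$pos != jb$pos

  pal <- is_palindromic(ja$effect_allele, ja$other_allele) |
    is_palindromic(jb$effect_allele, jb$other_allele)

  same <- jb$effect_allele == ja$effect_allele & jb$other_allele == ja$other_allele
  swap <- jb$effect_allele == ja$other_allele & jb$other_allele == ja$effect_allele
  comp_ea <- unname(DNA_COMPLEMENT[jb$effect_allele])
  comp_oa <- unname(DNA_COMPLEMENT[jb$other_allele])
  comp <- comp_ea == ja$effect_allele & comp_oa == ja$other_allele
  comp_swap <- comp_ea == ja$other_allele & comp_oa == ja$effect_allele
  mismatch <- !(same | swap | comp | comp_swap)

  drop <- discordant | mismatch | (drop_palindromic & pal)
  reason <- rep(NA_character_, nrow(ja))
  reason[mismatch] <- "allele_mismatch"
  reason[drop_palindromic & pal] <- "palindromic"
  reason[discordant] <- "discordant_position"

  keep <- !drop
  # direct match takes priority over the strand-complement interpretation, so
  # retained palindromic SNPs are aligned under the same-strand assumption
  flip_all <- ifelse(same, FALSE, ifelse(swap, TRUE, ifelse(comp, FALSE, TRUE)))
  flipped <- flip_all[keep]
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    snp_id = ja$snp_id[keep],
                    chrom = ja$chrom[keep],
                    pos = ja$pos[keep],
                    effect_allele = ja$effect_allele[keep],
                    other_allele = ja$other_allele[keep],
                    beta_a = ja$beta[keep],
                    se_a = ja$se[keep],
                    p_a = ja$p[keep],
                    beta_b = ifelse(flipped, -jb$beta[keep], jb$beta[keep]),
                    se_b = jb$se[keep],
                    p_b = jb$p[keep],
                    flipped = flipped)
  if (nrow(out) == 0L) stop("no overlapping SNPs could be harmonized")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  drops <- c(non_overlap = non_overlap,
             discordant_position = sum(reason == "discordant_position", na.rm = TRUE),
             palindromic = sum(reason == "palindromic", na.rm = TRUE),
             allele_mismatch = sum(reason == "allele_mismatch", na.rm = TRUE))
  structure(out, drops = drops, class = c("harmonized_pair", "data.frame"))
}

#' @export
print.harmonized_pair <- function(x, ...) {
  d <- drop_report(x)
  cat(sprintf("Harmonized two-trait table: %d SNPs (%d flipped to align alleles)\n",
              nrow(x), sum(x$flipped)))
  cat("study-B records dropped:",
      paste(sprintf("%s=%d", names(d), d), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a harmonized pair table and its drop report
#' @param pair A `harmonized_pair` object.
#' @param path Output TSV path; the drop report is written to
#'   `paste0(path, ".drops.txt")` as key-value text.
#' @export
write_pair <- function(pair, path) {
  utils::write.table(as.data.frame(pair), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  d <- drop_report(pair)
  writeLines(sprintf("%s\t%d", names(d), d), paste0(path, ".drops.txt"))
  invisible(path)
}

#' Read a harmonized pair table written by [write_pair()]
#' @param path TSV path.
#' @return A `harmonized_pair` object (drop report re-read if present).
#' @export
read_pair <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  dpath <- paste0(path, ".drops.txt")
  drops <- if (file.exists(dpath)) {
    kv <- utils::read.delim(dpath, header = FALSE, stringsAsFactors = FALSE)
    stats::setNames(as.integer(kv$V2), kv$V1)
  } else NULL
  structure(out, drops = drops, class = c("harmonized_pair", "data.frame"))
}
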