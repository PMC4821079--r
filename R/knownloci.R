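# Cross-query of established genome-wide-significant lead SNPs against the
# other trait's summary statistics, with Bonferroni correction over the SNPs
# actually testable.

#' Cross-query known lead SNPs in the other trait
#'
#' Looks up each previously reported lead SNP in the other trait's summary
#' statistics. Leads absent from the table are excluded from the Bonferroni
#' denominator (only SNPs actually testable count), so the per-SNP threshold
#' is `family_alpha / n_testable`. The other trait's effect is aligned to the
#' lead's effect allele before the direction comparison; a lead whose alleles
#' cannot be reconciled is excluded.
#'
#' @param leads Data frame of lead SNPs: `snp_id`, `effect_allele`, `beta`
#'   (the source trait's effect for the direction comparison); an optional
#'   `other_allele` column enables full allele checking.
#' @param other A validated `sumstats` for the other trait.
#' @param family_alpha Family-wise significance level in `(0, 1)`
#'   (default 0.05).
#' @return A `cross_query` list: `results` data frame (`snp_id`, `p`, `beta`
#'   aligned to the lead's effect allele, `significant`,
#'   `direction_agreement`), `excluded` data frame (`snp_id`, `reason`),
#'   `n_testable`, `bonferroni_alpha`.
#' @export
cross_query <- function(leads, other, family_alpha = 0.05) {
  stopifnot(is.data.frame(leads), nrow(leads) >= 1,
            all(c("snp_id", "effect_allele", "beta") %in% names(leads)),
            inherits(other, "sumstats"),
            family_alpha > 0, family_alpha < 1)
  i <- match(leads$snp_id, other$snp_id)
  found <- !is.na(i)

  le <- toupper(leads$effect_allele)
  oe <- other$effect_allele[i]
  oo <- other$other_allele[i]
  same <- found & (oe == le | unname(DNA_COMPLEMENT[oe]) == le)
  swap <- found & !same & (oo == le | unname(DNA_COMPLEMENT[oo]) == le)
  if ("other_allele" %in% names(leads)) {
    lo <- toupper(leads$other_allele)
    same <- same & (oo == lo | unname(DNA_COMPLEMENT[oo]) == lo)
    swap <- swap & (oe == lo | unname(DNA_COMPLEMENT[oe]) == lo)
  }
  testable <- found & (same | swap)

  excluded <- data.frame(snp_id = leads$snp_id[!testable],
                         reason = ifelse(!found[!testable],
                                         "absent_from_table",
                                         "allele_mismatch"),
                         stringsAsFactors = FALSE)
  n_testable <- sum(testable)
  if (n_testable == 0L) stop("no lead SNP is testable in the other trait")
  alpha_adj <- family_alpha / n_testable

  beta_other <- other$beta[i[testable]]
  beta_other[swap[testable]] <- -beta_other[swap[testable]]
  p_other <- other$p[i[testable]]
  results <- data.frame(snp_id = leads$snp_id[testable],
                        p = p_other,
                        beta = beta_other,
                        significant = p_other <= alpha_adj,
                        direction_agreement =
                          sign(beta_other) == sign(leads$beta[testable]),
                        stringsAsFactors = FALSE)
  structure(list(results = results, excluded = excluded,
                 n_testable = n_testable, bonferroni_alpha = alpha_adj,
                 family_alpha = family_alpha),
            class = "cross_query")
}

#' @export
print.cross_query <- function(x, ...) {
  cat(sprintf("Cross-query of %d lead SNP(s): %d testable, threshold %.3g (= %.2f / %d)\n",
              x$n_testable + nrow(x$excluded), x$n_testable,
              x$bonferroni_alpha, x$family_alpha, x$n_testable))
  cat(sprintf("%d significant in the other trait; %d direction-concordant\n",
              sum(x$results$significant), sum(x$results$direction_agreement)))
  if (nrow(x$excluded)) {
    cat("excluded:", paste(sprintf("%s (%s)", x$excluded$snp_id,
                                   x$excluded$reason), collapse = ", "), "\n")
  }
  invisible(x)
}
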