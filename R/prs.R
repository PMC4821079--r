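# Tiered polygenic risk scoring and covariate-adjusted logistic association.

#' Select a tier of risk SNPs from a discovery GWAS
#'
#' All SNPs with association p at or below the threshold, carrying the effect
#' allele and the log odds ratio as scoring weight. No LD pruning is applied:
#' tiers are deliberately non-pruned to maximize sensitivity. Typical tiers
#' are strong (5e-8), moderate (1e-4) and weak (1e-2).
#'
#' @param source A validated `sumstats` (the discovery trait).
#' @param threshold P-value cutoff.
#' @param tier Optional tier label (defaults to the formatted threshold).
#' @return A `risk_snp_set`: data frame `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`, with attributes `threshold` and `tier`.
#'   An empty selection triggers a warning and downstream scoring refuses it.
#' @export
select_risk_snps <- function(source, threshold, tier = NULL) {
  stopifnot(inherits(source, "sumstats"), threshold > 0, threshold <= 1)
  sel <- source$p <= threshold
  if (!any(sel)) warning("no SNPs pass the threshold; risk set is empty")
  structure(data.frame(snp_id = source$snp_id[sel],
                       effect_allele = source$effect_allele[sel],
                       other_allele = source$other_allele[sel],
                       weight = source$beta[sel],
                       stringsAsFactors = FALSE),
            threshold = threshold,
            tier = tier %||% format(threshold),
            class = c("risk_snp_set", "data.frame"))
}

#' Score a cohort with a weighted risk-SNP set
#'
#' Per-individual score: sum over risk SNPs present in the cohort of allele
#' dosage times log-odds-ratio weight. Cohort dosages are reconciled to the
#' risk set's effect alleles first: when the cohort counts the other allele
#' (directly or on the opposite strand), dosage `d` enters as `2 - d`.
#' Risk SNPs absent from the cohort, or with irreconcilable alleles, are
#' skipped and counted; missing per-individual dosages are skipped for that
#' individual and counted.
#'
#' @param cohort A `cohort`.
#' @param riskset A `risk_snp_set`.
#' @return Numeric score vector (one per individual) with attributes
#'   `n_used`, `n_absent`, `n_mismatch`, `missing_per_individual`, and
#'   `high_missingness` (`TRUE`, with a warning, when over half the risk set
#'   is unusable).
#' @export
score_cohort <- function(cohort, riskset) {
  stopifnot(inherits(cohort, "cohort"), inherits(riskset, "risk_snp_set"))
  if (nrow(riskset) == 0L) stop("refusing to score with an empty risk-SNP set")
  loc <- match(riskset$snp_id, cohort$map$snp_id)
  present <- !is.na(loc)
  n_absent <- sum(!present)

  ce <- cohort$map$effect_allele[loc[present]]
  co <- cohort$map$other_allele[loc[present]]
  re <- riskset$effect_allele[present]
  same <- ce == re | unname(DNA_COMPLEMENT[ce]) == re
  flip <- co == re | unname(DNA_COMPLEMENT[co]) == re
  usable <- same | flip
  n_mismatch <- sum(!usable)

  cols <- loc[present][usable]
  w <- riskset$weight[present][usable]
  flip_use <- flip[usable] & !same[usable]

  d <- cohort$dosage[, cols, drop = FALSE]
  if (any(flip_use)) {
    d[, flip_use] <- 2 - d[, flip_use, drop = FALSE]
  }
  na <- is.na(d)
  miss_per_ind <- rowSums(na)
  if (any(na)) d[na] <- 0
  scores <- drop(d %*% w)

  frac_unusable <- (n_absent + n_mismatch) / nrow(riskset)
  high <- frac_unusable > 0.5
  if (high) {
    warning(sprintf("%.0f%% of risk-set SNPs unusable in this cohort",
                    100 * frac_unusable))
  }
  structure(scores, n_used = length(w), n_absent = n_absent,
            n_mismatch = n_mismatch, missing_per_individual = miss_per_ind,
            high_missingness = high)
}

#' Logistic regression of phenotype on a standardized risk score
#'
#' Fits `phenotype ~ score + sex + cohort` by logistic regression, with the
#' score standardized to unit standard deviation so the reported odds ratio
#' is per 1 SD of score. Cohort labels are dummy-coded against the first
#' level. Constant covariates are dropped with a warning. Apparent separation
#' or non-convergence is flagged rather than reported as an estimate.
#'
#' @param scores Numeric per-individual scores (from [score_cohort()]).
#' @param cohort The `cohort` the scores belong to.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A `score_fit` list: `or` (per SD), `ci` (length 2), `p` (Wald),
#'   `beta`, `se`, `n_cases`, `n_controls`, `converged`, `dropped_covariates`.
#' @export
fit_score_model <- function(scores, cohort, conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort"), length(scores) == length(cohort$phenotype))
  y <- cohort$phenotype
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one case and one control")
  }
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("score has zero variance; cannot standardize")
  dat <- data.frame(y = y, score = (scores - mean(scores)) / s,
                    sex = cohort$sex, cohort = cohort$cohort_label)
  dropped <- character(0)
  rhs <- "score"
  if (length(unique(dat$sex)) > 1) rhs <- c(rhs, "sex") else dropped <- c(dropped, "sex")
  if (nlevels(droplevels(dat$cohort)) > 1) {
    dat$cohort <- droplevels(dat$cohort)
    rhs <- c(rhs, "cohort")
  } else dropped <- c(dropped, "cohort")
  if (length(dropped)) {
    warning("constant covariate(s) dropped: ", paste(dropped, collapse = ", "))
  }
  fit <- stats::glm(stats::reformulate(rhs, "y"), data = dat,
                    family = stats::binomial())
  co <- summary(fit)$coefficients
  b <- co["score", "Estimate"]
  se <- co["score", "Std. Error"]
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 50 && abs(b) < 50
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = if (converged) exp(b) else NA_real_,
                 ci = if (converged) exp(b + c(-1, 1) * zq * se) else c(NA_real_, NA_real_),
                 p = if (converged) co["score", "Pr(>|z|)"] else NA_real_,
                 beta = b, se = se,
                 n_cases = sum(y), n_controls = sum(1 - y),
                 converged = converged, dropped_covariates = dropped),
            class = "score_fit")
}

#' @export
print.score_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Score model did not converge (possible separation)\n")
  } else {
    cat(sprintf("OR per SD of score: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                x$or, x$ci[1], x$ci[2], x$p))
  }
  cat(sprintf("%d cases / %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Run the full tiered polygenic-score analysis
#'
#' Builds one risk-SNP set per threshold from the discovery summary
#' statistics, scores the cohort with each, and fits the adjusted logistic
#' model, returning one row per tier.
#'
#' @param cohort A `cohort`.
#' @param source Discovery-trait `sumstats`.
#' @param thresholds Named or unnamed vector of tier thresholds
#'   (default `c(strong = 5e-8, moderate = 1e-4, weak = 1e-2)`).
#' @return Data frame: `tier`, `threshold`, `n_snps`, `or`, `ci_low`,
#'   `ci_high`, `p`, `converged`.
#' @export
prs_tiers <- function(cohort, source,
                      thresholds = c(strong = 5e-8, moderate = 1e-4, weak = 1e-2)) {
  labels <- names(thresholds) %||% format(thresholds)
  if (is.null(names(thresholds))) names(thresholds) <- labels
  rows <- lapply(seq_along(thresholds), function(i) {
    rs <- suppressWarnings(select_risk_snps(source, thresholds[i],
                                            tier = names(thresholds)[i]))
    if (nrow(rs) == 0L) {
      return(data.frame(tier = names(thresholds)[i], threshold = thresholds[[i]],
                        n_snps = 0L, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, converged = FALSE))
    }
    sc <- score_cohort(cohort, rs)
    ft <- fit_score_model(sc, cohort)
    data.frame(tier = names(thresholds)[i], threshold = thresholds[[i]],
               n_snps = nrow(rs), or = ft$or, ci_low = ft$ci[1],
               ci_high = ft$ci[2], p = ft$p, converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
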