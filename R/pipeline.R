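# End-to-end orchestration of the four analysis stages from one validated
# configuration, with seeded per-stage substreams and a run manifest.

#' Build and validate a pipeline run configuration
#'
#' Collects input paths, stage toggles, all analysis thresholds and the run
#' seed into one validated object. Every stage's parameters are validated
#' here, before any stage runs. Defaults carry the analysis constants:
#' pruning r2 0.05; overlap cutoffs 1e-2..1e-6 flagged at corrected p < 0.01;
#' score tiers 5e-8 / 1e-4 / 1e-2; 100,000 overlap and 1,000 window-scan
#' permutations; 99.95th-percentile window threshold.
#'
#' @param inputs Named list of paths: `sumstats_a`, `sumstats_b` (required
#'   for the harmonize stage), `panel_prefix` (overlap), `cohort_prefix`
#'   (prs), `leads_a`, `leads_b` (knownloci), optional `sub1`, `sub2`
#'   (subtype annotation in cpsm), optional `pair` (pre-harmonized table when
#'   the harmonize stage is disabled).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer run seed; every stage derives its own substream from
#'   it, so toggling one stage does not perturb another's randomness.
#' @param stages Named logical list enabling `harmonize`, `overlap`, `prs`,
#'   `cpsm`, `knownloci` (all `TRUE` by default).
#' @param r2_threshold,cutoffs,flag_alpha Overlap-stage parameters.
#' @param n_perm_overlap Overlap permutations (default 1e5).
#' @param tiers Score-tier thresholds.
#' @param window_size,step,min_snps,percentile,n_perm_cpsm,merge_gap
#'   Window-scan parameters.
#' @param family_alpha Known-loci family-wise alpha.
#' @param drop_palindromic Passed to [align_alleles()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(inputs, out_dir, seed,
                       stages = list(),
                       r2_threshold = 0.05, cutoffs = 10^-(2:6),
                       flag_alpha = 0.01, n_perm_overlap = 100000,
                       tiers = c(strong = 5e-8, moderate = 1e-4, weak = 1e-2),
                       window_size = 100, step = 50, min_snps = 10,
                       percentile = 0.9995, n_perm_cpsm = 1000,
                       merge_gap = 50000, family_alpha = 0.05,
                       drop_palindromic = TRUE) {
  st <- list(harmonize = TRUE, overlap = TRUE, prs = TRUE, cpsm = TRUE,
             knownloci = TRUE)
  bad <- setdiff(names(stages), names(st))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  st[names(stages)] <- stages
  stopifnot(is.list(inputs), length(seed) == 1, is.finite(seed),
            r2_threshold >= 0, r2_threshold <= 1,
            all(cutoffs > 0 & cutoffs <= 1),
            flag_alpha > 0, flag_alpha < 1, n_perm_overlap >= 1,
            all(tiers > 0 & tiers <= 1),
            window_size >= min_snps, min_snps >= 2, step >= 1,
            percentile > 0, percentile < 1, n_perm_cpsm >= 1,
            merge_gap >= 0, family_alpha > 0, family_alpha < 1)
  need <- function(stage, fields) {
    if (isTRUE(st[[stage]])) {
      miss <- fields[!fields %in% names(inputs)]
      if (length(miss)) {
        stop("stage '", stage, "' enabled but input(s) missing: ",
             paste(miss, collapse = ", "))
      }
    }
  }
  need("harmonize", c("sumstats_a", "sumstats_b"))
  need("overlap", "panel_prefix")
  need("prs", c("cohort_prefix", "sumstats_b"))
  need("knownloci", c("leads_a", "leads_b"))
  if (!isTRUE(st$harmonize) && (isTRUE(st$overlap) || isTRUE(st$cpsm))) {
    need("overlap", "pair")
  }
  structure(list(inputs = inputs, out_dir = out_dir, seed = as.integer(seed),
                 stages = st, r2_threshold = r2_threshold, cutoffs = cutoffs,
                 flag_alpha = flag_alpha, n_perm_overlap = n_perm_overlap,
                 tiers = tiers, window_size = window_size, step = step,
                 min_snps = min_snps, percentile = percentile,
                 n_perm_cpsm = n_perm_cpsm, merge_gap = merge_gap,
                 family_alpha = family_alpha,
                 drop_palindromic = drop_palindromic),
            class = "run_config")
}

#' Run the cross-phenotype pipeline end to end
#'
#' Executes harmonize, overlap, prs, cpsm and knownloci in order, skipping
#' disabled stages, writing each stage's tables under the configured output
#' directory, echoing the configuration, and recording a run manifest (seed,
#' versions, input checksums, outputs). A stage failure halts the run with a
#' stage-tagged error; earlier stages' outputs are preserved. Given the same
#' configuration and seed, outputs are identical between runs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo <- unclass(config)
  echo$tiers <- as.list(echo$tiers)  # keep tier names through YAML
  yaml::write_yaml(echo, file.path(out, "config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()
  outputs <- character(0)
  pair <- NULL
  sumstats_b <- NULL

  if (isTRUE(config$stages$harmonize)) {
    results$harmonize <- stage("harmonize", {
      a <- read_sumstats(config$inputs$sumstats_a)
      sumstats_b <- read_sumstats(config$inputs$sumstats_b)
      pair <- align_alleles(a, sumstats_b,
                             drop_palindromic = config$drop_palindromic)
      write_pair(pair, file.path(out, "pair.tsv"))
      outputs <- c(outputs, "pair.tsv", "pair.tsv.drops.txt")
      pair
    })
  } else if (!is.null(config$inputs$pair)) {
    pair <- read_pair(config$inputs$pair)
  }

  if (isTRUE(config$stages$overlap)) {
    results$overlap <- stage("overlap", {
      panel <- read_panel(config$inputs$panel_prefix)
      pruned <- ld_prune(pair, panel = panel,
                         r2_threshold = config$r2_threshold)
      scan <- overlap_scan(pair, pruned, cutoffs = config$cutoffs,
                           flag_alpha = config$flag_alpha)
      perm <- permute_overlap(pair, pruned, cutoffs = config$cutoffs,
                              n_perm = config$n_perm_overlap,
                              seed = derive_seed(config$seed, 2L))
      scan$perm_p <- perm$perm_p[match(scan$cutoff, perm$cutoff)]
      conc <- lapply(scan$cutoff, function(cf) {
        direction_concordance(pair, pruned, cf)
      })
      scan$concordant <- vapply(conc, `[[`, 0L, "concordant")
      scan$conc_total <- vapply(conc, `[[`, 0L, "total")
      scan$conc_binom_p <- vapply(conc, `[[`, 0, "p")
      utils::write.table(scan, file.path(out, "overlap_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "overlap_table.tsv")
      list(pruned = pruned, table = scan)
    })
  }

  if (isTRUE(config$stages$prs)) {
    results$prs <- stage("prs", {
      if (is.null(sumstats_b)) {
        sumstats_b <- read_sumstats(config$inputs$sumstats_b)
      }
      cohort <- read_cohort(config$inputs$cohort_prefix)
      tiers <- prs_tiers(cohort, sumstats_b, thresholds = config$tiers)
      utils::write.table(tiers, file.path(out, "prs_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rs <- suppressWarnings(select_risk_snps(sumstats_b,
                                              max(config$tiers), "widest"))
      scores <- if (nrow(rs)) score_cohort(cohort, rs) else numeric(0)
      utils::write.table(data.frame(individual = seq_along(scores),
                                    score = as.numeric(scores)),
                         file.path(out, "prs_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "prs_results.tsv", "prs_scores.tsv")
      tiers
    })
  }

  if (isTRUE(config$stages$cpsm)) {
    results$cpsm <- stage("cpsm", {
      profiles <- transform_profiles(pair)
      windows <- scan_windows(profiles, window_size = config$window_size,
                              step = config$step, min_snps = config$min_snps)
      thr <- permutation_threshold(profiles,
                                   window_size = config$window_size,
                                   step = config$step,
                                   min_snps = config$min_snps,
                                   n_perm = config$n_perm_cpsm,
                                   percentile = config$percentile,
                                   seed = derive_seed(config$seed, 4L))
      regions <- call_regions(windows, pair, thr,
                              merge_gap = config$merge_gap)
      ann <- NULL
      if (!is.null(config$inputs$sub1) && !is.null(config$inputs$sub2) &&
          nrow(regions) > 0) {
        ann <- annotate_subtypes(regions, pair,
                                 read_sumstats(config$inputs$sub1),
                                 read_sumstats(config$inputs$sub2))
        regions <- ann$regions
        writeLines(sprintf("%s\t%s", names(ann$summary),
                           vapply(ann$summary, format, "")),
                   file.path(out, "cpsm_subtypes.txt"))
        outputs <- c(outputs, "cpsm_subtypes.txt")
      }
      utils::write.table(as.data.frame(regions),
                         file.path(out, "cpsm_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_regions_bed(regions, file.path(out, "cpsm_regions.bed"))
      outputs <- c(outputs, "cpsm_regions.tsv", "cpsm_regions.bed")
      list(threshold = thr, regions = regions, subtype = ann)
    })
  }

  if (isTRUE(config$stages$knownloci)) {
    results$knownloci <- stage("knownloci", {
      if (is.null(sumstats_b)) {
        sumstats_b <- read_sumstats(config$inputs$sumstats_b)
      }
      sumstats_a <- read_sumstats(config$inputs$sumstats_a)
      qa <- cross_query(utils::read.delim(config$inputs$leads_a,
                                          stringsAsFactors = FALSE),
                        sumstats_b, family_alpha = config$family_alpha)
      qb <- cross_query(utils::read.delim(config$inputs$leads_b,
                                          stringsAsFactors = FALSE),
                        sumstats_a, family_alpha = config$family_alpha)
      utils::write.table(qa$results, file.path(out, "knownloci_a_in_b.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(qb$results, file.path(out, "knownloci_b_in_a.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "knownloci_a_in_b.tsv", "knownloci_b_in_a.tsv")
      list(a_in_b = qa, b_in_a = qb)
    })
  }

  input_paths <- unlist(config$inputs, use.names = TRUE)
  sums <- vapply(input_paths, function(p) {
    files <- if (file.exists(p)) p else Sys.glob(paste0(p, "*"))
    if (!length(files)) return(NA_character_)
    paste(unname(tools::md5sum(files)), collapse = ",")
  }, "")
  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("pleiomap"))),
    sprintf("r_version\t%s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed\t%d", config$seed),
    sprintf("stages\t%s",
            paste(names(config$stages)[unlist(config$stages)], collapse = ",")),
    sprintf("input_md5\t%s=%s", names(sums), sums),
    sprintf("output\t%s", outputs)
  )
  writeLines(manifest, file.path(out, "manifest.txt"))
  invisible(results)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(args$tiers)) args$tiers <- unlist(args$tiers)
  if (!is.null(args$cutoffs)) args$cutoffs <- unlist(args$cutoffs)
  do.call(run_config, args)
}
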