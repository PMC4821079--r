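# GWAS summary-statistics container and readers.

SUMSTATS_REQUIRED <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                       "beta", "se", "p")
SUMSTATS_OPTIONAL <- c("n_cases", "n_controls")

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-delimited per-SNP association table (one GWAS), maps its column
#' names onto the standard schema, validates every row against the domain
#' invariants, and returns a `sumstats` object sorted by `(chrom, pos)`.
#' Malformed rows (p outside (0,1], non-positive standard error, invalid or
#' identical alleles, chromosome outside 1-22, duplicated SNP id) are dropped,
#' counted by reason, and reported with their line numbers.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping standard field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `p`, and optionally `n_cases`, `n_controls`) to the column names used in
#'   the file. Fields absent from the map are assumed to use the standard name.
#' @param sep Field separator (default tab).
#' @return A `sumstats` object: a data frame with the standard columns, sorted
#'   by chromosome and position, carrying a `drops` attribute (named integer
#'   vector of per-reason drop counts).
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL)
  cm <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad)) stop("unknown fields in column_map: ", paste(bad, collapse = ", "))
    cm[names(column_map)] <- unname(column_map)
  }
  missing_req <- SUMSTATS_REQUIRED[!cm[SUMSTATS_REQUIRED] %in% names(raw)]
  if (length(missing_req)) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(cm[missing_req], collapse = ", "))
  }
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   snp_id = as.character(raw[[cm["snp_id"]]]),
                   chrom = suppressWarnings(as.integer(raw[[cm["chrom"]]])),
                   pos = suppressWarnings(as.numeric(raw[[cm["pos"]]])),
                   effect_allele = toupper(as.character(raw[[cm["effect_allele"]]])),
                   other_allele = toupper(as.character(raw[[cm["other_allele"]]])),
                   beta = suppressWarnings(as.numeric(raw[[cm["beta"]]])),
                   se = suppressWarnings(as.numeric(raw[[cm["se"]]])),
                   p = suppressWarnings(as.numeric(raw[[cm["p"]]])))
  for (f in SUMSTATS_OPTIONAL) {
    df[[f]] <- if (cm[f] %in% names(raw)) {
      suppressWarnings(as.integer(raw[[cm[f]]]))
    } else NA_integer_
  }
  as_sumstats(df, line_offset = 1L)
}

#' Validate a data frame of per-SNP association results
#'
#' Applies the `sumstats` domain invariants to an in-memory data frame: drops
#' and counts invalid rows, enforces unique SNP ids (first occurrence kept),
#' and sorts by `(chrom, pos)`.
#'
#' @param df Data frame with the standard summary-statistics columns.
#' @param line_offset Added to row indices when reporting dropped lines
#'   (use 1 when rows came from a file with a header).
#' @return A validated `sumstats` object with a `drops` attribute.
#' @export
as_sumstats <- function(df, line_offset = 0L) {
  need <- setdiff(SUMSTATS_REQUIRED, names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  for (f in SUMSTATS_OPTIONAL) if (!f %in% names(df)) df[[f]] <- NA_integer_
  df <- df[, c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL)]

  reasons <- list(
    bad_p = !is.finite(df$p) | df$p <= 0 | df$p > 1,
    bad_se = !is.finite(df$se) | df$se <= 0,
    bad_beta = !is.finite(df$beta),
    bad_alleles = !is_acgt(df$effect_allele) | !is_acgt(df$other_allele) |
      df$effect_allele == df$other_allele,
    bad_position = !is.finite(df$chrom) | is.na(df$chrom) | df$chrom < 1 |
      df$chrom > 22 | !is.finite(df$pos) | df$pos < 1
  )
  bad <- Reduce(`|`, reasons)
  bad[is.na(bad)] <- TRUE
  # attribute each bad row to the first failing reason
  drops <- first_reason_counts(reasons)
  if (any(bad)) {
    message(sum(bad), " malformed row(s) dropped (lines ",
            paste(utils::head(which(bad) + line_offset, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")")
  }
  df <- df[!bad, , drop = FALSE]

  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    message(sum(dup), " duplicated snp_id row(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  drops <- c(drops, duplicate_id = sum(dup))

  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, drops = drops, class = c("sumstats", "data.frame"))
}

# helpers for per-reason accounting: each bad row counts under its first reason
first_reason_counts <- function(reasons) {
  m <- do.call(cbind, lapply(reasons, function(r) { r[is.na(r)] <- TRUE; r }))
  first <- apply(m, 1L, function(row) if (any(row)) which(row)[1L] else 0L)
  counts <- tabulate(first[first > 0L], nbins = length(reasons))
  stats::setNames(as.integer(counts), names(reasons))
}

#' Per-reason drop counts recorded during validation or harmonization
#' @param x A `sumstats` or `harmonized_pair` object.
#' @return Named integer vector of drop counts.
#' @export
drop_report <- function(x) attr(x, "drops")

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d SNPs, chromosomes %s\n",
              nrow(x), paste(range(x$chrom), collapse = "-")))
  d <- drop_report(x)
  if (!is.null(d) && sum(d) > 0) {
    cat("rows dropped at validation:",
        paste(sprintf("%s=%d", names(d)[d > 0], d[d > 0]), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a summary-statistics table to a tab-delimited file
#' @param x A `sumstats` object (or data frame with the standard columns).
#' @param path Output file path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
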