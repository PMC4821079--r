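# Plain-text import/export of panels and cohorts.

#' Write a reference panel as dosage + SNP metadata TSVs
#'
#' Writes `<prefix>_dosage.tsv` (individuals x SNPs, header = SNP ids) and
#' `<prefix>_snps.tsv` (SNP metadata including block assignment and MAF).
#'
#' @param panel A `ref_panel`.
#' @param prefix Output path prefix.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "ref_panel"))
  utils::write.table(panel$dosage, paste0(prefix, "_dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- panel$map
  meta$within_block_rho <- panel$spec$within_block_rho
  meta$snps_per_block <- panel$spec$snps_per_block
  meta$seed <- panel$seed
  utils::write.table(meta, paste0(prefix, "_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a reference panel written by [write_panel()]
#' @param prefix Path prefix used at write time.
#' @return A `ref_panel`.
#' @export
read_panel <- function(prefix) {
  dosage <- as.matrix(utils::read.delim(paste0(prefix, "_dosage.tsv"),
                                        check.names = FALSE))
  meta <- utils::read.delim(paste0(prefix, "_snps.tsv"),
                            stringsAsFactors = FALSE)
  spec <- ld_block_spec(n_blocks = max(meta$block),
                        snps_per_block = meta$snps_per_block[1],
                        within_block_rho = meta$within_block_rho[1],
                        maf_range = range(meta$maf),
                        n_chrom = max(meta$chrom))
  map <- meta[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "block", "maf")]
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, spec = spec,
                 seed = meta$seed[1]),
            class = "ref_panel")
}

#' Write a cohort as dosage + phenotype TSVs
#'
#' Writes `<prefix>_dosage.tsv` (individuals x SNPs), `<prefix>_pheno.tsv`
#' (phenotype, sex, cohort label) and `<prefix>_snps.tsv` (counted alleles).
#'
#' @param cohort A `cohort`.
#' @param prefix Output path prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.table(cohort$dosage, paste0(prefix, "_dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ph <- data.frame(phenotype = cohort$phenotype, sex = cohort$sex,
                   cohort_label = as.integer(cohort$cohort_label))
  utils::write.table(ph, paste0(prefix, "_pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$map, paste0(prefix, "_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a cohort written by [write_cohort()]
#' @param prefix Path prefix used at write time.
#' @return A `cohort`.
#' @export
read_cohort <- function(prefix) {
  dosage <- as.matrix(utils::read.delim(paste0(prefix, "_dosage.tsv"),
                                        check.names = FALSE))
  ph <- utils::read.delim(paste0(prefix, "_pheno.tsv"))
  map <- utils::read.delim(paste0(prefix, "_snps.tsv"),
                           stringsAsFactors = FALSE)
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map,
                 phenotype = ph$phenotype, sex = ph$sex,
                 cohort_label = factor(ph$cohort_label), seed = NA),
            class = "cohort")
}
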