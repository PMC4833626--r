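## Genotype QC: missing-data filters and one-SNP-per-RAD-locus selection.
##
## Thresholds are strict inequalities: an individual is removed only when its
## missing fraction EXCEEDS max_missing, so boundary values are retained.
## The canonical order (applied by qc_filter) is individuals first, then
## loci, then first-SNP selection; the order matters because each filter
## changes the missingness denominators of the other.

#' Filter individuals by missing-data fraction
#'
#' Removes individuals whose fraction of missing calls is strictly greater
#' than `max_missing`; order is preserved. Removed ids are attached as
#' attribute `removed`.
#'
#' @param x a [genotype_matrix()].
#' @param max_missing retention threshold (default 0.25: drop individuals
#'   with more than 25% missing calls).
#' @return filtered `genotype_matrix`.
#' @export
filter_individuals <- function(x, max_missing = 0.25) {
  if (n_individuals(x) == 0) stop("empty genotype matrix")
  miss <- rowMeans(is.na(x$geno))
  keep <- miss <= max_missing
  if (!any(keep))
    warning("all individuals removed by the missing-data filter")
  out <- x[which(keep), ]
  attr(out, "removed") <- x$individuals$id[!keep]
  out
}

#' Filter loci by missing-data fraction
#'
#' Removes SNPs whose fraction of missing calls is strictly greater than
#' `max_missing` (default 0.10). Removed locus keys are attached as
#' attribute `removed`.
#'
#' @inheritParams filter_individuals
#' @export
filter_loci <- function(x, max_missing = 0.10) {
  if (n_loci(x) == 0) stop("empty genotype matrix")
  miss <- colMeans(is.na(x$geno))
  keep <- miss <= max_missing
  if (!any(keep))
    warning("all loci removed by the missing-data filter")
  out <- x[, which(keep)]
  attr(out, "removed") <- colnames(x$geno)[!keep]
  out
}

#' Keep only the first SNP of each RAD locus
#'
#' Retains, for every RAD locus, the SNP with the smallest offset within the
#' tag, avoiding explicitly linked SNPs. Deterministic; duplicate offsets
#' within a locus are an error (offsets must be unique).
#'
#' @param x a [genotype_matrix()].
#' @return `genotype_matrix` with one SNP per RAD locus, in the original
#'   locus order.
#' @export
select_first_snp <- function(x) {
  lc <- x$loci
  if (anyDuplicated(paste(lc$locus_id, lc$snp_pos)))
    stop("tied SNP offsets within a RAD locus; offsets must be unique")
  min_pos <- tapply(lc$snp_pos, lc$locus_id, min)
  keep <- lc$snp_pos == min_pos[as.character(lc$locus_id)]
  x[, which(keep)]
}

#' Run the full QC chain
#'
#' Individuals filter, then loci filter, then first-SNP selection, with a
#' machine-readable report.
#'
#' @inheritParams filter_individuals
#' @param max_missing_individual,max_missing_locus thresholds for the two
#'   filters.
#' @return list of class `qc_report`: `matrix` (the filtered
#'   `genotype_matrix`), `removed_individuals`, `removed_loci`,
#'   `n_snps_collapsed`, missingness histograms.
#' @export
qc_filter <- function(x, max_missing_individual = 0.25,
                      max_missing_locus = 0.10) {
  step1 <- filter_individuals(x, max_missing_individual)
  step2 <- filter_loci(step1, max_missing_locus)
  step3 <- select_first_snp(step2)
  rep <- list(
    matrix = step3,
    removed_individuals = attr(step1, "removed"),
    removed_loci = attr(step2, "removed"),
    n_snps_collapsed = n_loci(step2) - n_loci(step3),
    missing_by_individual = rowMeans(is.na(x$geno)),
    missing_by_locus = colMeans(is.na(x$geno)),
    thresholds = c(individual = max_missing_individual,
                   locus = max_missing_locus))
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  individuals removed (> %.0f%% missing): %d\n",
              100 * x$thresholds["individual"],
              length(x$removed_individuals)))
  cat(sprintf("  SNPs removed (> %.0f%% missing): %d\n",
              100 * x$thresholds["locus"], length(x$removed_loci)))
  cat(sprintf("  linked SNPs collapsed to first-per-locus: %d\n",
              x$n_snps_collapsed))
  print(x$matrix)
  invisible(x)
}
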