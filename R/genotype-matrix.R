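#' Diploid SNP genotype matrix with individual and locus metadata
#'
#' The central data container of the package. Genotypes are stored as
#' alternate-allele dosages: `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) or `NA` (missing call). All loci are biallelic
#' SNPs located on short RAD loci (93 bp tags by convention); a RAD locus may
#' carry several SNPs, distinguished by their 1-based offset within the tag.
#'
#' @param geno integer matrix, individuals x loci, values in `{0, 1, 2, NA}`.
#' @param individuals data frame with columns `id`, `site` and optionally
#'   `group` (lineage label, may be `NA`); one row per row of `geno`.
#' @param loci data frame with columns `locus_id` (RAD locus identifier),
#'   `snp_pos` (1-based offset of the SNP within the tag), `ref` and `alt`
#'   (allele nucleotides); one row per column of `geno`.
#' @return An object of class `genotype_matrix`: a list with elements `geno`,
#'   `individuals` and `loci`. Row names of `geno` are individual ids and
#'   column names are `"<locus_id>:<snp_pos>"` keys.
#' @examples
#' gm <- genotype_matrix(
#'   rbind(a = c(0, 1), b = c(2, NA)),
#'   data.frame(id = c("a", "b"), site = "S1"),
#'   data.frame(locus_id = c("L1", "L2"), snp_pos = c(10, 4),
#'              ref = c("A", "C"), alt = c("G", "T")))
#' gm
#' @export
genotype_matrix <- function(geno, individuals, loci) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("id", "site") %in% names(individuals)))
    stop("'individuals' needs columns 'id' and 'site'")
  if (!"group" %in% names(individuals)) individuals$group <- NA_character_
  if (!all(c("locus_id", "snp_pos") %in% names(loci)))
    stop("'loci' needs columns 'locus_id' and 'snp_pos'")
  if (!"ref" %in% names(loci)) loci$ref <- "A"
  if (!"alt" %in% names(loci)) loci$alt <- "T"
  if (nrow(individuals) != nrow(geno))
    stop("nrow(individuals) != nrow(geno)")
  if (nrow(loci) != ncol(geno))
    stop("nrow(loci) != ncol(geno)")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(individuals$id))
    stop("duplicated individual ids")
  key <- locus_key(loci)
  if (anyDuplicated(key))
    stop("duplicated (locus_id, snp_pos) pairs")
  rownames(geno) <- individuals$id
  colnames(geno) <- key
  structure(list(geno = geno, individuals = individuals, loci = loci),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

locus_key <- function(loci) paste(loci$locus_id, loci$snp_pos, sep = ":")

#' Number of individuals / loci
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname n_individuals
#' @export
n_loci <- function(x) ncol(x$geno)

#' Subset a genotype matrix
#'
#' `x[i, j]` keeps individuals `i` and loci `j` (any usual index type),
#' keeping metadata in step.
#'
#' @param x a `genotype_matrix`.
#' @param i,j individual and locus indices.
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  ii <- setNames(seq_len(nrow(x$geno)), rownames(x$geno))[i]
  jj <- setNames(seq_len(ncol(x$geno)), colnames(x$geno))[j]
  genotype_matrix(x$geno[ii, jj, drop = FALSE],
                  x$individuals[ii, , drop = FALSE],
                  x$loci[jj, , drop = FALSE])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d RAD loci)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$loci$locus_id))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$geno))))
  grp <- x$individuals$group
  if (any(!is.na(grp))) {
    tb <- table(grp, useNA = "ifany")
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  cat("  sites:", paste(sort(unique(x$individuals$site)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  list(n_individuals = nrow(object$geno),
       n_snps = ncol(object$geno),
       n_rad_loci = length(unique(object$loci$locus_id)),
       missing_fraction = mean(is.na(object$geno)),
       missing_by_individual = rowMeans(is.na(object$geno)),
       missing_by_locus = colMeans(is.na(object$geno)))
}

#' Per-individual observed heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls, per individual.
#'
#' @param x a `genotype_matrix` or a dosage matrix/vector.
#' @return named numeric vector.
#' @export
individual_heterozygosity <- function(x) {
  g <- if (is_genotype_matrix(x)) x$geno else x
  if (is.null(dim(g))) return(mean(g == 1L, na.rm = TRUE))
  rowMeans(g == 1L, na.rm = TRUE)
}

## internal: resolve a grouping argument into a factor over individuals
resolve_grouping <- function(x, grouping) {
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(x$individuals)) {
    f <- x$individuals[[grouping]]
  } else {
    if (length(grouping) != nrow(x$geno))
      stop("grouping must name a metadata column or give one value per individual")
    f <- grouping
  }
  factor(f)
}
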