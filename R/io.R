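## Readers and writers: VCF (GT-only, biallelic, contig = RAD locus id,
## POS = 1-based SNP offset within the tag), a TSV genotype-matrix dialect
## carrying individual metadata inline, outline CSVs and trait TSVs.

#' Write genotypes to VCF or TSV
#'
#' The VCF dialect is VCFv4.2, GT-only, one contig per RAD locus, POS the
#' 1-based SNP offset within the 93-bp tag; missing calls are `./.`.
#' Individual site/group metadata does not fit in VCF and is written to
#' `<path>.meta.tsv` alongside. The TSV dialect is self-contained: columns
#' `id`, `site`, `group`, then one column per SNP keyed
#' `locus:pos:ref:alt`, dosage values with `NA` for missing.
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @param seed optional seed to record in the file header.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("tsv", "vcf"), seed = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    wide <- data.frame(id = x$individuals$id, site = x$individuals$site,
                       group = x$individuals$group, x$geno,
                       check.names = FALSE)
    names(wide)[-(1:3)] <- paste(x$loci$locus_id, x$loci$snp_pos,
                                 x$loci$ref, x$loci$alt, sep = ":")
    con <- file(path, "w")
    writeLines(sprintf("# cryptline genotype matrix%s",
                       if (is.null(seed)) "" else paste0("; seed=", seed)),
               con)
    write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    con <- file(path, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##source=cryptline%s",
                         if (is.null(seed)) "" else paste0(";seed=", seed)),
                 sprintf("##contig=<ID=%s,length=93>",
                         unique(x$loci$locus_id)),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", x$individuals$id),
                       collapse = "\t")), con)
    gt <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
    gt[is.na(gt)] <- "./."
    lines <- paste(x$loci$locus_id, x$loci$snp_pos,
                   paste(x$loci$locus_id, x$loci$snp_pos, sep = ":"),
                   x$loci$ref, x$loci$alt, ".", "PASS", ".", "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
    close(con)
    write.table(x$individuals, paste0(path, ".meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' Inverse of [write_genotypes()]: `write -> read` is lossless for calls,
#' metadata and locus order. Multiallelic VCF records are rejected with
#' their ids; malformed TSV rows are reported with line numbers.
#'
#' @param path input file.
#' @param format `"tsv"`, `"vcf"`, or `NULL` to guess from the extension.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    if (length(lines) < 2) stop("not a cryptline genotype TSV: ", path)
    header <- strsplit(lines[1], "\t")[[1]]
    if (!identical(header[1:3], c("id", "site", "group")))
      stop("not a cryptline genotype TSV (expected id/site/group columns)")
    keys <- header[-(1:3)]
    parts <- strsplit(keys, ":")
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop("malformed locus keys in header: ", paste(keys[bad], collapse = ", "))
    body <- strsplit(lines[-1], "\t")
    badrow <- which(lengths(body) != length(header))
    if (length(badrow))
      stop("malformed rows (wrong field count) at line(s): ",
           paste(badrow + 1, collapse = ", "))
    M <- do.call(rbind, body)
    geno <- suppressWarnings(matrix(as.integer(M[, -(1:3), drop = FALSE]),
                                    nrow = nrow(M)))
    loci <- data.frame(locus_id = vapply(parts, `[`, "", 1),
                       snp_pos = as.integer(vapply(parts, `[`, "", 2)),
                       ref = vapply(parts, `[`, "", 3),
                       alt = vapply(parts, `[`, "", 4))
    grp <- M[, 3]
    grp[grp == "NA"] <- NA
    genotype_matrix(geno,
                    data.frame(id = M[, 1], site = M[, 2], group = grp),
                    loci)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      stop("multiallelic records not supported: ",
           paste(fix[multi, "ID"], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- function(g) {
      out <- rep(NA_integer_, length(g))
      out[g %in% c("0/0", "0|0")] <- 0L
      out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
      out[g %in% c("1/1", "1|1")] <- 2L
      out
    }
    geno <- t(apply(gt, 1, conv))
    colnames(geno) <- colnames(gt)
    meta_path <- paste0(path, ".meta.tsv")
    inds <- if (file.exists(meta_path)) {
      read.table(meta_path, header = TRUE, sep = "\t",
                 colClasses = "character")
    } else {
      data.frame(id = colnames(gt), site = NA_character_,
                 group = NA_character_)
    }
    inds <- inds[match(colnames(gt), inds$id), ]
    genotype_matrix(t(geno),
                    inds,
                    data.frame(locus_id = fix[, "CHROM"],
                               snp_pos = as.integer(fix[, "POS"]),
                               ref = fix[, "REF"], alt = fix[, "ALT"]))
  }
}

#' Write / read a single outline CSV
#'
#' One file per leaflet: two columns x, y, one point per row, contour closed
#' implicitly.
#'
#' @param outline matrix with columns x, y.
#' @param path file path.
#' @return `path` (write) or the outline matrix (read).
#' @export
write_outline_csv <- function(outline, path) {
  write.table(data.frame(x = outline[, 1], y = outline[, 2]), path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",")
  if (!all(c("x", "y") %in% names(d)) || nrow(d) < 3)
    stop("not an outline CSV (need x,y columns, >= 3 points): ", path)
  as.matrix(d[, c("x", "y")])
}
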