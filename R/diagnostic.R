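## Diagnostic-locus assay: selection of lineage-diagnostic SNPs suitable for
## a small melt-curve-style genotyping panel, and assignment of new samples
## from partial genotypes at panel loci.

## internal: validate a bipartition of group labels
check_partition <- function(partition, groups) {
  if (!is.list(partition) || length(partition) != 2)
    stop("partition must be a list of two group sets")
  all_p <- unlist(partition)
  if (anyDuplicated(all_p) || !setequal(all_p, groups))
    stop("partition must split the groups into two non-overlapping sides ",
         "covering all groups")
  partition
}

#' Find loci diagnostic for a bipartition of lineages
#'
#' A locus is diagnostic when every group is monomorphic there (all
#' non-missing calls homozygous for one allele; groups with no calls
#' disqualify the locus) and the two partition sides carry different alleles.
#' Such loci have per-locus F_ST of 1 between the partition sides.
#'
#' @param x a QC-filtered [genotype_matrix()].
#' @param grouping group labels (column name or vector); hybrids must be
#'   excluded or unassigned (`NA` labels are dropped).
#' @param partition list of two vectors of group labels, e.g.
#'   `list("lineage_1", c("lineage_2", "lineage_3"))`.
#' @return data frame: `locus_id`, `snp_pos`, `key`, `allele_side1`,
#'   `allele_side2` (nucleotides fixed on each side), `support` (smallest
#'   per-group non-missing call count backing the call).
#' @export
find_diagnostic_loci <- function(x, grouping = "group", partition) {
  fac <- resolve_grouping(x, grouping)
  keep <- !is.na(fac)
  geno <- x$geno[keep, , drop = FALSE]
  fac <- droplevels(fac[keep])
  groups <- levels(fac)
  partition <- check_partition(partition, groups)
  cc <- group_counts(geno, fac)
  n <- cc$n; alt <- cc$alt; het <- cc$het
  ## monomorphic within group: no heterozygotes and allele count 0 or 2n
  mono <- het == 0 & (alt == 0 | alt == 2 * n) & n >= 1
  allele <- ifelse(alt == 0, 0L, 2L)          # fixed dosage per group
  all_mono <- colSums(mono) == length(groups)
  s1 <- partition[[1]]; s2 <- partition[[2]]
  same_side <- function(side) {
    a <- allele[side, , drop = FALSE]
    apply(a, 2, function(v) length(unique(v)) == 1)
  }
  ok <- all_mono & same_side(s1) & same_side(s2) &
    allele[s1[1], ] != allele[s2[1], ]
  idx <- which(ok)
  support <- apply(n[, idx, drop = FALSE], 2, min)
  dosage_to_base <- function(d, i) ifelse(d == 0L, x$loci$ref[i], x$loci$alt[i])
  data.frame(locus_id = x$loci$locus_id[idx],
             snp_pos = x$loci$snp_pos[idx],
             key = colnames(x$geno)[idx],
             allele_side1 = dosage_to_base(allele[s1[1], idx], idx),
             allele_side2 = dosage_to_base(allele[s2[1], idx], idx),
             dosage_side1 = unname(allele[s1[1], idx]),
             support = unname(support),
             row.names = NULL)
}

#' Filter diagnostic candidates for assay suitability
#'
#' A candidate survives when its RAD tag carries exactly one variable site
#' across the sampled alleles and that site has at least `flank` invariant
#' bases on each side (a documented proxy for "suitable priming sites" in a
#' short-amplicon melt assay). Tags whose sequence length differs from
#' `tag_length` are flagged and excluded.
#'
#' @param candidates data frame from [find_diagnostic_loci()].
#' @param rad_sequences data frame `locus_id`, `ref_seq`, `alt_seq` (the two
#'   haplotype sequences of each tag).
#' @param flank minimum invariant bases on each side of the SNP.
#' @param tag_length expected tag length (93 by convention).
#' @return the surviving subset of `candidates`, with columns `n_variable`
#'   and `var_pos` added; excluded rows are attached as attribute
#'   `excluded` with a `reason`.
#' @export
filter_assay_suitable <- function(candidates, rad_sequences, flank = 18,
                                  tag_length = 93) {
  m <- match(candidates$locus_id, rad_sequences$locus_id)
  if (anyNA(m)) stop("missing tag sequences for some candidate loci")
  reason <- character(nrow(candidates))
  nvar <- integer(nrow(candidates))
  vpos <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    rs <- rad_sequences$ref_seq[m[i]]
    as_ <- rad_sequences$alt_seq[m[i]]
    if (nchar(rs) != tag_length || nchar(as_) != tag_length) {
      reason[i] <- "tag length differs from expected"
      next
    }
    diffs <- which(strsplit(rs, "")[[1]] != strsplit(as_, "")[[1]])
    nvar[i] <- length(diffs)
    if (length(diffs) != 1) {
      reason[i] <- "more than one variable site in tag"
      next
    }
    vpos[i] <- diffs
    if (diffs - 1 < flank || tag_length - diffs < flank)
      reason[i] <- "insufficient invariant flank for priming"
  }
  keep <- reason == ""
  out <- candidates[keep, , drop = FALSE]
  out$n_variable <- nvar[keep]
  out$var_pos <- vpos[keep]
  excl <- candidates[!keep, , drop = FALSE]
  if (nrow(excl)) excl$reason <- reason[!keep]
  attr(out, "excluded") <- excl
  out
}

#' Build a diagnostic panel
#'
#' Selects `k` loci for a partition, deterministically: highest minor-group
#' sample support first, ties broken by locus id. Fewer than `k` suitable
#' loci yields all of them with a warning.
#'
#' @param suitable data frame from [filter_assay_suitable()] (or
#'   [find_diagnostic_loci()]).
#' @param partition the bipartition the loci are diagnostic for (carried
#'   into the panel).
#' @param k loci to select.
#' @return list of class `diagnostic_panel`: `partition`, `loci` (the chosen
#'   rows).
#' @export
build_panel <- function(suitable, partition, k = 4) {
  o <- order(-suitable$support, suitable$locus_id)
  if (nrow(suitable) < k) {
    warning(sprintf("only %d suitable loci available (%d requested)",
                    nrow(suitable), k))
    k <- nrow(suitable)
  }
  structure(list(partition = partition,
                 loci = suitable[o[seq_len(k)], , drop = FALSE]),
            class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf("diagnostic panel: {%s} vs {%s}, %d loci\n",
              paste(x$partition[[1]], collapse = ","),
              paste(x$partition[[2]], collapse = ","),
              nrow(x$loci)))
  print.data.frame(x$loci[, c("locus_id", "snp_pos", "allele_side1",
                              "allele_side2", "support")],
                   row.names = FALSE)
  invisible(x)
}

#' Assign samples to lineages from panel genotypes
#'
#' Each panel votes through its loci: a homozygous call for a side's allele
#' is evidence for that side, a heterozygous call is evidence for both sides
#' (reported, never collapsed). Votes are combined across the two panels by
#' intersecting the group sets they admit. Alleles specific to incompatible
#' sides -- contradictory homozygous calls within a panel, or an empty
#' intersection across panels (e.g. evidence for both the isolated group of
#' one partition and the isolated group of the other) -- give `conflict`;
#' a non-singleton intersection or too few informative calls gives
#' `insufficient`.
#'
#' @param x a [genotype_matrix()] holding the samples to assign (only panel
#'   loci are consulted; others are ignored).
#' @param panels list of two `diagnostic_panel` objects for the two
#'   partitions (e.g. group 1 vs rest, and groups 1+2 vs 3).
#' @param conflict_rule `"any"` (default: any evidence for incompatible
#'   sides is a conflict, matching the discard-outright field practice) or
#'   `"majority"` (contradictory homozygous calls within a panel resolve to
#'   the majority side; exact ties remain conflicts).
#' @return data frame of class `assignment_result`: `id`, `label` (group id,
#'   `"conflict"` or `"insufficient"`), `evidence` (collapsed per-panel side
#'   calls), `het_panel_calls` (count of heterozygous panel calls).
#' @export
assign_samples <- function(x, panels, conflict_rule = c("any", "majority")) {
  conflict_rule <- match.arg(conflict_rule)
  stopifnot(length(panels) == 2)
  all_groups <- unique(unlist(lapply(panels, function(p) unlist(p$partition))))
  labels <- character(n_individuals(x))
  evid <- character(n_individuals(x))
  hets <- integer(n_individuals(x))
  for (i in seq_len(n_individuals(x))) {
    sets <- vector("list", 2)
    panel_evid <- character(2)
    conflict <- FALSE
    for (p in 1:2) {
      pan <- panels[[p]]
      keys <- pan$loci$key
      present <- keys %in% colnames(x$geno)
      g <- x$geno[i, keys[present]]
      d1 <- pan$loci$dosage_side1[present]
      informative <- !is.na(g)
      g <- g[informative]; d1 <- d1[informative]
      if (!length(g)) {
        sets[p] <- list(NULL)
        panel_evid[p] <- "none"
        next
      }
      side1 <- g == d1          # homozygous for side-1 allele
      side2 <- g == 2L - d1
      het <- g == 1L
      hets[i] <- hets[i] + sum(het)
      has1 <- any(side1) || any(het)
      has2 <- any(side2) || any(het)
      hom_contradiction <- any(side1) && any(side2)
      if (hom_contradiction) {
        if (conflict_rule == "any" || sum(side1) == sum(side2)) {
          conflict <- TRUE
        } else {                       # majority rule resolves the panel
          sets[[p]] <- pan$partition[[if (sum(side1) > sum(side2)) 1 else 2]]
          panel_evid[p] <- paste0("majority{",
                                  paste(sets[[p]], collapse = ","), "}")
          next
        }
      }
      sets[[p]] <- if (any(het)) unlist(pan$partition) else
        if (has1 && !has2) pan$partition[[1]] else
          if (has2 && !has1) pan$partition[[2]] else unlist(pan$partition)
      panel_evid[p] <- paste0(
        if (has1) paste0("{", paste(pan$partition[[1]], collapse = ","), "}"),
        if (has1 && has2) "+",
        if (has2) paste0("{", paste(pan$partition[[2]], collapse = ","), "}"))
    }
    evid[i] <- paste(panel_evid, collapse = " | ")
    informative_panels <- !vapply(sets, is.null, TRUE)
    if (!any(informative_panels)) {
      labels[i] <- "insufficient"
      next
    }
    cand <- Reduce(intersect, c(list(all_groups), sets[informative_panels]))
    labels[i] <- if (conflict || length(cand) == 0) "conflict"
      else if (length(cand) == 1) cand
      else "insufficient"
  }
  out <- data.frame(id = x$individuals$id, label = labels, evidence = evid,
                    het_panel_calls = hets)
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Panel-based lineage assignment\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
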