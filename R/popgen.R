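## Descriptive population genetics: diversity summaries, Nei's standard
## genetic distance, Weir-Cockerham F_ST, and genotype PCA.

## internal: per-group per-locus counts. fac: factor over individuals.
## Returns matrices (groups x loci): n (non-missing diploid calls),
## alt (alternate-allele count), het (heterozygote count).
group_counts <- function(geno, fac) {
  ok <- !is.na(geno)
  g0 <- geno
  g0[!ok] <- 0L
  list(n   = rowsum(ok + 0L, fac),
       alt = rowsum(g0, fac),
       het = rowsum((ok & geno == 1L) + 0L, fac))
}

#' Alternate-allele frequencies by group
#'
#' @param x a [genotype_matrix()].
#' @param grouping metadata column name (`"group"` or `"site"`) or a vector of
#'   labels, one per individual.
#' @return numeric matrix, loci x groups, of alternate-allele frequencies
#'   (`NaN` where a group has no calls at a locus).
#' @export
allele_freqs <- function(x, grouping = "group") {
  fac <- resolve_grouping(x, grouping)
  keep <- !is.na(fac)
  cc <- group_counts(x$geno[keep, , drop = FALSE], droplevels(fac[keep]))
  t(cc$alt / (2 * cc$n))
}

#' Per-group diversity summary
#'
#' Computes, for each group of a partition, the standard diversity panel for
#' highly selfing populations: sample size `n`, observed heterozygosity `Ho`
#' (mean over loci of the heterozygote fraction among non-missing calls),
#' unbiased expected heterozygosity `He` (Nei's gene diversity with
#' small-sample correction, `n/(n-1) * (1 - sum p^2 - Ho/(2n))` per locus),
#' the inbreeding coefficient `Fis = 1 - Ho/He`, allelic richness `AR`
#' (alleles per locus rarefied, per locus, to the smallest group's non-missing
#' allele count at that locus), the private-allele count `PA` (alleles seen in
#' this group and no other) and `pctPA` (`PA` as a percentage of all alleles
#' observed in the group).
#'
#' Known hybrid individuals should be excluded by the caller before computing
#' by-group private alleles.
#'
#' @inheritParams allele_freqs
#' @return data frame of class `group_summary`, one row per group, columns
#'   `group, n, Ho, He, Fis, AR, PA, pctPA`.
#' @export
group_summary <- function(x, grouping = "group") {
  fac <- resolve_grouping(x, grouping)
  if (any(is.na(fac)))
    stop("every individual must be assigned to a group (drop unassigned first)")
  cc <- group_counts(x$geno, fac)
  groups <- rownames(cc$n)
  nvec <- as.vector(table(fac)[groups])

  p <- cc$alt / (2 * cc$n)                  # groups x loci
  q <- 1 - p
  ho_l <- cc$het / cc$n
  n <- cc$n
  he_l <- (n / (n - 1)) * (1 - p^2 - q^2 - ho_l / (2 * n))
  he_l[n < 2] <- NA
  he_l <- pmax(he_l, 0)

  Ho <- rowMeans(replace(ho_l, n < 1, NA), na.rm = TRUE)
  He <- rowMeans(he_l, na.rm = TRUE)
  Fis <- ifelse(He > 0, 1 - Ho / He, NA_real_)

  ## allelic richness, rarefied per locus to the smallest group's allele count
  gmin <- 2 * apply(n, 2, min)
  valid <- gmin >= 2
  AR <- rep(NA_real_, length(groups))
  if (any(valid)) {
    n2 <- 2 * n[, valid, drop = FALSE]
    altc <- cc$alt[, valid, drop = FALSE]
    gg <- matrix(gmin[valid], nrow = nrow(n2), ncol = ncol(n2), byrow = TRUE)
    rare_term <- function(Na) {
      ## P(allele with count Na present in a subsample of size g)
      1 - exp(lchoose(n2 - Na, gg) - lchoose(n2, gg))
    }
    AR <- rowMeans(rare_term(altc) + rare_term(n2 - altc))
  }

  ## private alleles over this partition
  alt_pres <- cc$alt > 0
  ref_pres <- (2 * cc$n - cc$alt) > 0
  priv <- function(pres) {
    tot <- colSums(pres)
    sweep(pres, 2, tot, function(a, b) a & b == 1)
  }
  PA <- rowSums(priv(alt_pres)) + rowSums(priv(ref_pres))
  total_alleles <- rowSums(alt_pres) + rowSums(ref_pres)
  pctPA <- 100 * PA / total_alleles

  out <- data.frame(group = groups, n = nvec, Ho = Ho, He = He, Fis = Fis,
                    AR = AR, PA = PA, pctPA = pctPA, row.names = NULL)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat("Per-group diversity summary\n")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Nei's standard genetic distance
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` where `Jx`, `Jy` and `Jxy` are the gene
#' identities (sums of squared / cross-multiplied allele frequencies) averaged
#' over loci. Loci with a missing frequency in either population are dropped
#' pairwise. For biallelic loci pass the alternate-allele frequency vectors.
#'
#' @param p_a,p_b alternate-allele frequency vectors on the same loci.
#' @return distance (non-negative; `Inf` with a warning when the populations
#'   share no allelic identity, `Jxy = 0`).
#' @export
neis_distance <- function(p_a, p_b) {
  if (length(p_a) != length(p_b)) stop("frequency vectors differ in length")
  keep <- is.finite(p_a) & is.finite(p_b)
  p_a <- p_a[keep]; p_b <- p_b[keep]
  if (!length(p_a)) stop("no loci with frequencies in both populations")
  jx <- mean(p_a^2 + (1 - p_a)^2)
  jy <- mean(p_b^2 + (1 - p_b)^2)
  jxy <- mean(p_a * p_b + (1 - p_a) * (1 - p_b))
  if (jxy <= 0) {
    warning("zero shared identity between populations; distance is infinite")
    return(Inf)
  }
  max(-log(jxy / sqrt(jx * jy)), 0)
}

#' Weir-Cockerham F_ST
#'
#' Per-locus and multilocus theta from the Weir-Cockerham (1984) variance
#' components a (among populations), b (among individuals within populations)
#' and c (within individuals), for biallelic SNPs. The estimator does not
#' assume Hardy-Weinberg proportions (the observed heterozygote frequency
#' enters the components directly), which matters for highly selfing
#' organisms. The multilocus estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)`, not the mean of per-locus ratios.
#'
#' A locus contributes only if at least two populations have non-missing
#' calls there and the locus is not monomorphic overall; skipped loci are
#' counted. Negative per-locus estimates are retained (see `truncate`).
#'
#' @inheritParams allele_freqs
#' @param truncate if `TRUE`, clamp negative per-locus estimates to zero for
#'   display; the multilocus estimate always uses untruncated components.
#' @return list of class `wc_fst` with `per_locus` (named vector, `NA` for
#'   skipped loci), `multilocus`, `n_loci_used`, `n_skipped`.
#' @export
wc_fst <- function(x, grouping = "group", truncate = FALSE) {
  fac <- resolve_grouping(x, grouping)
  if (nlevels(droplevels(fac[!is.na(fac)])) < 2)
    stop("F_ST needs at least two populations")
  keep <- !is.na(fac)
  geno <- x$geno[keep, , drop = FALSE]
  fac <- droplevels(fac[keep])
  cc <- group_counts(geno, fac)
  n <- cc$n
  pres <- n >= 1

  r <- colSums(pres)
  nsum <- colSums(n)
  nbar <- nsum / r
  n2sum <- colSums(n^2)
  p <- ifelse(n > 0, cc$alt / (2 * n), 0)
  h <- ifelse(n > 0, cc$het / n, 0)

  pbar <- colSums(n * p) / nsum
  hbar <- colSums(n * h) / nsum
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  nc <- (nsum - n2sum / nsum) / (r - 1)

  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc_ <- hbar / 2

  denom <- a + b + cc_
  usable <- r >= 2 & nbar > 1 & is.finite(denom) & abs(denom) > 1e-300
  theta <- rep(NA_real_, ncol(geno))
  theta[usable] <- a[usable] / denom[usable]
  names(theta) <- colnames(geno)
  multi <- sum(a[usable]) / sum(denom[usable])
  per_locus <- if (truncate) pmax(theta, 0) else theta
  structure(list(per_locus = per_locus, multilocus = multi,
                 n_loci_used = sum(usable), n_skipped = sum(!usable)),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST: multilocus theta = %.4f (%d loci used, %d skipped)\n",
              x$multilocus, x$n_loci_used, x$n_skipped))
  invisible(x)
}

#' All pairwise group divergences
#'
#' Nei's D and Weir-Cockerham theta (multilocus and per-locus) for every pair
#' of groups in the partition.
#'
#' @inheritParams allele_freqs
#' @return list of class `pairwise_divergence`: data frame `pairs` with
#'   columns `group_a, group_b, neis_D, fst_multilocus` and a list
#'   `per_locus_fst` of per-locus theta vectors named `"A|B"`.
#' @export
pairwise_divergence <- function(x, grouping = "group") {
  fac <- resolve_grouping(x, grouping)
  keep <- !is.na(fac)
  groups <- levels(droplevels(fac[keep]))
  if (length(groups) < 2) stop("need at least two groups")
  freqs <- allele_freqs(x, grouping)
  pairs <- utils::combn(groups, 2)
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    neis_D = NA_real_, fst_multilocus = NA_real_)
  per_locus <- list()
  for (k in seq_len(ncol(pairs))) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    res$neis_D[k] <- neis_distance(freqs[, ga], freqs[, gb])
    sel <- keep & fac %in% c(ga, gb)
    sub <- x[which(sel), ]
    w <- wc_fst(sub, as.character(fac[sel]))
    res$fst_multilocus[k] <- w$multilocus
    per_locus[[paste(ga, gb, sep = "|")]] <- w$per_locus
  }
  structure(list(pairs = res, per_locus_fst = per_locus),
            class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat("Pairwise divergence between groups\n")
  print.data.frame(format(x$pairs, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Principal component analysis of genotypes
#'
#' Genotypes are taken as alternate-allele dosages, missing calls are
#' mean-imputed per locus, and columns are centered (not variance-scaled)
#' before eigendecomposition, the convention of standard SNP-PCA tools.
#'
#' @param x a [genotype_matrix()], ideally QC-filtered.
#' @param n_components number of axes to retain.
#' @return list of class `genotype_pca`: `scores` (individuals x components),
#'   `variance_fraction` (per retained axis, relative to total variance) and
#'   `sdev` (all singular values / sqrt(n-1)).
#' @export
genotype_pca <- function(x, n_components = 10) {
  g <- x$geno
  if (any(colSums(!is.na(g)) == 0))
    stop("loci with all calls missing must be removed before PCA")
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  k <- min(n_components, length(pc$sdev))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf[seq_len(k)],
                 sdev = pc$sdev),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype PCA: %d individuals, %d axes retained\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.genotype_pca <- function(x, col = 1, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_fraction[2]),
                 ...)
  invisible(x)
}

## internal: mean silhouette width over a score matrix and a clustering
avg_silhouette <- function(scores, cl) {
  d <- as.matrix(dist(scores))
  cl <- as.integer(factor(cl))
  ks <- sort(unique(cl))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(length(cl))
  for (i in seq_along(cl)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ks[ks != cl[i]],
                    function(k) mean(d[i, cl == k]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Detect lineage clusters on PCA scores
#'
#' k-means over a range of cluster counts, choosing k by mean silhouette
#' width. Used by the pipeline to report the number of genetic lineages.
#'
#' @param pca a `genotype_pca` result (or a score matrix).
#' @param k_max largest cluster count to try.
#' @param seed optional RNG seed for k-means restarts.
#' @return list with `k`, `cluster` (labels), `silhouette` (per k).
#' @export
detect_lineages <- function(pca, k_max = 6, seed = NULL) {
  scores <- if (inherits(pca, "genotype_pca")) x_scores(pca) else pca
  k_max <- min(k_max, nrow(scores) - 1)
  run <- function() {
    sil <- setNames(rep(NA_real_, k_max - 1), 2:k_max)
    fits <- vector("list", k_max - 1)
    for (k in 2:k_max) {
      fit <- kmeans(scores, centers = k, nstart = 10)
      fits[[k - 1]] <- fit
      sil[k - 1] <- avg_silhouette(scores, fit$cluster)
    }
    best <- unname(which.max(sil))
    list(k = best + 1, cluster = fits[[best]]$cluster, silhouette = sil)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

x_scores <- function(p) p$scores[, 1:2, drop = FALSE]
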