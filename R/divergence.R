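## Divergence-island scan: per-locus F_ST distributions, shared high-F_ST
## loci between comparisons, a U-shape summary statistic, and the
## migrants-per-generation conversion for coalescent estimates.

#' Histogram of per-locus F_ST with a high-divergence count
#'
#' Bins per-locus estimates on `[0, 1]`. Negative estimates (the
#' Weir-Cockerham estimator can go below zero) are clamped into the lowest
#' bin and counted separately; `NA` loci are dropped and counted.
#'
#' @param fst numeric vector of per-locus F_ST values (e.g. from
#'   [wc_fst()]).
#' @param bins number of equal-width bins (a multiple of 10 keeps decile
#'   boundaries exact for [u_shape_index()]).
#' @param threshold high-divergence threshold (default 0.9).
#' @return list of class `fst_distribution`: `counts`, `breaks`,
#'   `n_above` (loci with F_ST strictly above `threshold`), `threshold`,
#'   `n_negative`, `n_na`, `n`.
#' @export
fst_distribution <- function(fst, bins = 20, threshold = 0.9) {
  if (!length(fst)) stop("empty F_ST vector")
  n_na <- sum(is.na(fst))
  v <- fst[!is.na(fst)]
  if (!length(v)) stop("no non-missing F_ST values")
  n_neg <- sum(v < 0)
  n_above <- sum(v > threshold)
  v <- pmin(pmax(v, 0), 1)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  structure(list(counts = counts, breaks = breaks, n_above = n_above,
                 threshold = threshold, n_negative = n_neg, n_na = n_na,
                 n = length(v)),
            class = "fst_distribution")
}

#' @export
print.fst_distribution <- function(x, ...) {
  cat(sprintf("per-locus F_ST distribution: %d loci, %d with F_ST > %.2f (u-shape index %.2f)\n",
              x$n, x$n_above, x$threshold, u_shape_index(x)))
  invisible(x)
}

#' @export
plot.fst_distribution <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$counts, names.arg = sprintf("%.2f", mids),
                    xlab = "per-locus F_ST", ylab = "loci", ...)
  invisible(x)
}

#' Loci exceeding the divergence threshold in two comparisons
#'
#' Set intersection of high-F_ST loci between two aligned per-locus vectors
#' (same loci, same order or shared names).
#'
#' @param fst_a,fst_b named per-locus F_ST vectors.
#' @param threshold divergence threshold (strictly above).
#' @return list with `ids` (shared outlier locus names) and `count`, plus
#'   the per-comparison outlier counts.
#' @export
shared_outliers <- function(fst_a, fst_b, threshold = 0.9) {
  if (is.null(names(fst_a)) || is.null(names(fst_b))) {
    if (length(fst_a) != length(fst_b))
      stop("unnamed F_ST vectors must align by position")
    names(fst_a) <- names(fst_b) <- paste0("locus", seq_along(fst_a))
  }
  common <- intersect(names(fst_a), names(fst_b))
  if (!length(common)) stop("comparisons share no loci")
  a <- names(fst_a)[!is.na(fst_a) & fst_a > threshold]
  b <- names(fst_b)[!is.na(fst_b) & fst_b > threshold]
  ids <- intersect(intersect(a, b), common)
  list(ids = ids, count = length(ids),
       count_a = sum(a %in% common), count_b = sum(b %in% common))
}

#' U-shape index of an F_ST distribution
#'
#' Summary of the visual contrast between a U-shaped distribution (high mass
#' at both extremes, as expected under divergence with gene flow and
#' divergence islands) and a unimodal low/central one (drift only). With
#' per-decile masses `m1..m10` on `[0, 1]`, the statistic is
#' `(2 * min(m1, m10) - mbar) / (2 * min(m1, m10) + mbar)` where `mbar` is
#' the mean per-decile mass of the middle deciles (values in `[0.3, 0.7)`).
#' It is `+1` when all mass sits at both extremes, negative when mass is
#' central or piles at only one end, and 0 for the degenerate empty case.
#' This package's own convention, not an inferential statistic.
#'
#' @param x an `fst_distribution`, or a numeric vector of per-locus F_ST.
#' @return value in `[-1, 1]`.
#' @export
u_shape_index <- function(x) {
  if (inherits(x, "fst_distribution")) {
    bins <- length(x$counts)
    if (bins %% 10 != 0)
      stop("u_shape_index needs bin counts aligned to deciles (multiple of 10)")
    per <- bins / 10
    dec <- vapply(1:10, function(d)
      sum(x$counts[((d - 1) * per + 1):(d * per)]), 0)
    dec <- dec / sum(dec)
  } else {
    v <- pmin(pmax(x[!is.na(x)], 0), 1)
    if (length(v) < 1) stop("empty F_ST vector")
    dec <- vapply(1:10, function(d)
      mean(v >= (d - 1) / 10 & (v < d / 10 | (d == 10 & v <= 1))), 0)
  }
  lo <- dec[1]; hi <- dec[10]
  mid <- mean(dec[4:7])
  e <- 2 * min(lo, hi)
  if (e + mid == 0) return(0)
  (e - mid) / (e + mid)
}

#' Migrants per generation from mutation-scaled coalescent estimates
#'
#' Converts a mutation-scaled population size `theta = 4 Ne mu` and a
#' mutation-scaled immigration rate `M = m / mu` into the expected number of
#' migrants per generation, `Ne m = theta * M / 4`. The coalescent sampler
#' producing theta and M is external; only the conversion arithmetic lives
#' here.
#'
#' @param theta mutation-scaled population size(s), non-negative.
#' @param M mutation-scaled migration rate(s), non-negative.
#' @return `Ne m` values (vectorized).
#' @export
migrants_per_generation <- function(theta, M) {
  if (any(theta < 0, na.rm = TRUE) || any(M < 0, na.rm = TRUE))
    stop("theta and M must be non-negative")
  theta * M / 4
}
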