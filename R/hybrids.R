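## Hybrid analysis: forward cross/self simulation, hybrid index, and
## classification of putative hybrids against simulated F1/F2/F3 clouds.

## An "individual" throughout is a numeric vector of alternate-allele
## dosages (0/1/2/NA), aligned to a common locus set.

as_dosage <- function(ind) {
  if (is_genotype_matrix(ind)) stop("pass a single dosage vector, not a matrix")
  ind
}

gamete <- function(d) {
  g <- integer(length(d))
  g[which(d == 2L)] <- 1L
  het <- which(d == 1L)
  if (length(het)) g[het] <- rbinom(length(het), 1L, 0.5)
  g[is.na(d)] <- NA_integer_
  g
}

#' Cross two individuals
#'
#' The offspring receives one uniformly chosen allele from each parent at
#' every locus, independently across loci (free recombination between RAD
#' loci). A missing call in either parent yields a missing offspring call.
#'
#' @param parent_a,parent_b dosage vectors (0/1/2/NA) on the same loci.
#' @param seed optional RNG seed.
#' @return offspring dosage vector.
#' @export
cross <- function(parent_a, parent_b, seed = NULL) {
  a <- as_dosage(parent_a); b <- as_dosage(parent_b)
  if (length(a) != length(b)) stop("parents genotyped on different locus sets")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("parents genotyped on different locus sets")
  with_seed(seed, gamete(a) + gamete(b))
}

#' Self-fertilize an individual
#'
#' Draws two independent gametes from the same individual: homozygous loci
#' breed true; heterozygous loci segregate 1/4 AA : 1/2 Aa : 1/4 aa.
#'
#' @param ind dosage vector.
#' @param seed optional RNG seed.
#' @return offspring dosage vector.
#' @export
self_individual <- function(ind, seed = NULL) {
  d <- as_dosage(ind)
  with_seed(seed, gamete(d) + gamete(d))
}

#' Simulate F1, F2 and F3 hybrid generations
#'
#' Mirrors the standard simulation protocol for selfing taxa: `n_sim` F1s are
#' produced by crossing individuals sampled (with replacement) from the two
#' parental populations; each F1 is selfed once to give an F2, and each F2
#' selfed once to give an F3. Individual observed heterozygosity and hybrid
#' index are recorded for every simulated individual.
#'
#' @param pop_a,pop_b parental populations: dosage matrices (individuals x
#'   loci) or `genotype_matrix` objects on the same loci.
#' @param n_sim simulated individuals per generation class (>= 2).
#' @param seed RNG seed.
#' @param index_method `"ml"` for the maximum-likelihood hybrid index (see
#'   [hybrid_index()]) or `"count"` for the fast counting estimator over
#'   fixed-difference loci.
#' @param parent_sampling `"individual"` (default: F1 gametes come from
#'   sampled parental individuals, preserving within-population structure)
#'   or `"frequency"` (gametes drawn directly from population allele
#'   frequencies, the convention of frequency-based hybrid simulators;
#'   provided for comparison).
#' @return object of class `hybrid_sim`: data frame `sims` (`class`, `het`,
#'   `index`), summary stats per class, parental allele frequencies, seed.
#' @export
simulate_hybrid_generations <- function(pop_a, pop_b, n_sim = 1000,
                                        seed = NULL,
                                        index_method = c("ml", "count"),
                                        parent_sampling = c("individual",
                                                            "frequency")) {
  index_method <- match.arg(index_method)
  parent_sampling <- match.arg(parent_sampling)
  A <- if (is_genotype_matrix(pop_a)) pop_a$geno else as.matrix(pop_a)
  B <- if (is_genotype_matrix(pop_b)) pop_b$geno else as.matrix(pop_b)
  if (ncol(A) != ncol(B)) stop("parental populations differ in locus sets")
  if (nrow(A) < 1 || nrow(B) < 1) stop("parental populations must be non-empty")
  if (n_sim < 2) stop("n_sim must be >= 2 (class SDs are undefined otherwise)")
  p_a <- colMeans(A, na.rm = TRUE) / 2
  p_b <- colMeans(B, na.rm = TRUE) / 2

  run <- function() {
    classes <- c("F1", "F2", "F3")
    het <- matrix(NA_real_, n_sim, 3, dimnames = list(NULL, classes))
    idx <- matrix(NA_real_, n_sim, 3, dimnames = list(NULL, classes))
    ia <- sample.int(nrow(A), n_sim, replace = TRUE)
    ib <- sample.int(nrow(B), n_sim, replace = TRUE)
    L <- ncol(A)
    for (i in seq_len(n_sim)) {
      f1 <- if (parent_sampling == "individual")
        cross(A[ia[i], ], B[ib[i], ]) else
        rbinom(L, 1L, p_a) + rbinom(L, 1L, p_b)
      f2 <- self_individual(f1)
      f3 <- self_individual(f2)
      gens <- list(F1 = f1, F2 = f2, F3 = f3)
      for (k in 1:3) {
        het[i, k] <- individual_heterozygosity(gens[[k]])
        idx[i, k] <- hybrid_index(gens[[k]], p_a, p_b,
                                  method = index_method,
                                  interval = FALSE)$h
      }
    }
    sims <- data.frame(class = rep(classes, each = n_sim),
                       het = as.vector(het), index = as.vector(idx))
    summ <- do.call(rbind, lapply(classes, function(cl) {
      s <- sims[sims$class == cl, ]
      data.frame(class = cl, mean_het = mean(s$het), sd_het = sd(s$het),
                 mean_index = mean(s$index), sd_index = sd(s$index))
    }))
    structure(list(sims = sims, summary = summ, freqs_a = p_a, freqs_b = p_b,
                   n_sim = n_sim, seed = seed, index_method = index_method,
                   parent_sampling = parent_sampling),
              class = "hybrid_sim")
  }
  with_seed(seed, run())
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cat(sprintf("Simulated hybrid generations (n = %d per class, index = %s)\n",
              x$n_sim, x$index_method))
  print.data.frame(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

## internal: per-locus data for the hybrid-index likelihood
index_loci <- function(ind, freqs_a, freqs_b) {
  g <- as_dosage(ind)
  keep <- !is.na(g) & is.finite(freqs_a) & is.finite(freqs_b) &
    freqs_a != freqs_b
  list(g = g[keep], pa = freqs_a[keep], pb = freqs_b[keep])
}

#' Maximum-likelihood hybrid index
#'
#' Estimates the proportion `h` of an individual's ancestry derived from
#' population B. Each allele is modelled as drawn from B with probability `h`
#' and from A otherwise, so the per-locus alternate-allele probability is
#' `q(h) = (1 - h) pA + h pB` and the genotype likelihood is binomial with
#' two draws. The log likelihood is concave in `h`; the maximizer is found by
#' root-finding on its analytic derivative. The reported interval is the
#' 2-log-likelihood-unit support region.
#'
#' With `method = "count"` only loci fixed for alternate alleles in the two
#' populations (`|pA - pB| = 1`) are used and the estimate is the fraction of
#' B-diagnostic alleles carried; this equals the ML estimate when all loci
#' are fixed differences and nothing is missing.
#'
#' @param ind dosage vector; missing loci are dropped.
#' @param freqs_a,freqs_b parental alternate-allele frequency vectors.
#' @param method `"ml"` or `"count"`.
#' @param interval compute the support interval? (Skipping it is faster in
#'   large simulations.)
#' @param support drop in log-likelihood units defining the interval.
#' @return list of class `hybrid_index`: `h`, `lower`, `upper`, `method`,
#'   `n_loci`.
#' @export
hybrid_index <- function(ind, freqs_a, freqs_b, method = c("ml", "count"),
                         interval = TRUE, support = 2) {
  method <- match.arg(method)
  L <- index_loci(ind, freqs_a, freqs_b)
  if (method == "count") {
    diag <- abs(L$pa - L$pb) == 1
    L <- list(g = L$g[diag], pa = L$pa[diag], pb = L$pb[diag])
  }
  if (!length(L$g))
    stop("no informative loci (identical or missing parental frequencies)")
  dpk <- L$pb - L$pa
  qh <- function(h) pmin(pmax(L$pa + h * dpk, 1e-12), 1 - 1e-12)
  loglik <- function(h) {
    q <- qh(h)
    sum(L$g * log(q) + (2 - L$g) * log1p(-q))
  }
  dldh <- function(h) {
    q <- qh(h)
    sum(dpk * (L$g / q - (2 - L$g) / (1 - q)))
  }
  eps <- 1e-9
  h_hat <- if (method == "count" && all(abs(dpk) == 1)) {
    ## closed form: fraction of B-diagnostic alleles
    sum(ifelse(dpk > 0, L$g, 2 - L$g)) / (2 * length(L$g))
  } else if (dldh(eps) <= 0) 0 else if (dldh(1 - eps) >= 0) 1 else
    uniroot(dldh, c(eps, 1 - eps), tol = 1e-13, maxiter = 1000)$root
  out <- list(h = h_hat, lower = NA_real_, upper = NA_real_,
              method = method, n_loci = length(L$g))
  if (interval) {
    lmax <- loglik(min(max(h_hat, eps), 1 - eps))
    target <- lmax - support
    f <- function(h) loglik(h) - target
    out$lower <- if (f(eps) >= 0) 0 else
      uniroot(f, c(eps, min(max(h_hat, eps), 1 - eps)), tol = 1e-10)$root
    out$upper <- if (f(1 - eps) >= 0) 1 else
      uniroot(f, c(min(max(h_hat, eps), 1 - eps), 1 - eps), tol = 1e-10)$root
  }
  class(out) <- "hybrid_index"
  out
}

#' @export
print.hybrid_index <- function(x, ...) {
  cat(sprintf("hybrid index (%s, %d loci): h = %.3f", x$method, x$n_loci, x$h))
  if (!is.na(x$lower)) cat(sprintf(" (%.3f-%.3f)", x$lower, x$upper))
  cat("\n")
  invisible(x)
}

#' Classify a putative hybrid against simulated generations
#'
#' Compares an observed (heterozygosity, hybrid index) pair against the
#' empirical F1/F2/F3 clouds from [simulate_hybrid_generations()]. For each
#' class a central `(1 - alpha)` per-margin percentile box is built; the
#' observation is scored by its normalized Chebyshev distance to each class
#' (max over margins of |obs - median| / box half-width). An observation in a
#' box takes that class; one within `extend` times a box (and nearest to it)
#' still takes the class; otherwise elevated heterozygosity with a strongly
#' skewed index is called `backcross-like`, near-zero heterozygosity with an
#' extreme index is `parental`, and anything else is `uncertain`.
#'
#' @param het observed individual heterozygosity.
#' @param index observed hybrid index.
#' @param sim a `hybrid_sim` object.
#' @param alpha per-margin tail mass excluded from each class box.
#' @param extend multiplier on box half-widths admitting near-miss members.
#' @param parental_het heterozygosity at or below which a non-hybrid
#'   (parental) call is possible.
#' @param id optional individual id carried into the result.
#' @return list of class `hybrid_call`: `label` (one of `F1`, `F2`, `F3`,
#'   `backcross-like`, `parental`, `uncertain`), `scores` per class, the
#'   percentile of the observation within each class margin, and the inputs.
#' @export
classify_hybrid <- function(het, index, sim, alpha = 0.05, extend = 2,
                            parental_het = 0.02, id = NULL) {
  stopifnot(inherits(sim, "hybrid_sim"))
  classes <- unique(sim$sims$class)
  if (!length(classes)) stop("simulation contains no classes")
  floor_hw <- 1e-3   # resolution floor: het/index granularity at ~1000s of loci
  boxes <- lapply(classes, function(cl) {
    s <- sim$sims[sim$sims$class == cl, ]
    qs <- function(v) quantile(v, c(alpha / 2, 0.5, 1 - alpha / 2),
                               names = FALSE)
    h <- qs(s$het); i <- qs(s$index)
    list(med = c(h[2], i[2]),
         hw = pmax(c((h[3] - h[1]) / 2, (i[3] - i[1]) / 2), floor_hw),
         pct = c(mean(s$het <= het), mean(s$index <= index)))
  })
  names(boxes) <- classes
  obs <- c(het, index)
  scores <- vapply(boxes, function(b) max(abs(obs - b$med) / b$hw), numeric(1))
  pct <- t(vapply(boxes, function(b) b$pct, numeric(2)))
  colnames(pct) <- c("het", "index")
  best <- names(scores)[which.min(scores)]
  smin <- min(scores)

  index_extreme <- all(vapply(boxes, function(b)
    abs(index - b$med[2]) > extend * b$hw[2], logical(1)))
  label <- if (smin <= extend) {
    best
  } else if (het <= parental_het && (index <= 0.1 || index >= 0.9)) {
    "parental"
  } else if (het > parental_het && index_extreme) {
    "backcross-like"
  } else {
    "uncertain"
  }
  structure(list(id = id, het = het, index = index, label = label,
                 scores = scores, percentiles = pct,
                 in_box = scores <= 1, alpha = alpha),
            class = "hybrid_call")
}

#' @export
print.hybrid_call <- function(x, ...) {
  cat(sprintf("hybrid call%s: %s (het = %.3f, index = %.3f)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$label, x$het, x$index))
  cat("  class scores:",
      paste(sprintf("%s=%.2f", names(x$scores), x$scores), collapse = ", "),
      "\n")
  invisible(x)
}

#' Flag putative hybrids on PCA scores
#'
#' Convention used by the pipeline (the source analyses identified candidates
#' visually): an individual is flagged when it is genuinely intermediate
#' between its two nearest lineage-cluster centroids (distance ratio above
#' `ratio`) and its observed heterozygosity exceeds `het_mult` times the
#' median heterozygosity of its nearest cluster.
#'
#' @param pca a `genotype_pca` result.
#' @param x the `genotype_matrix` behind the PCA.
#' @param cluster integer cluster labels (e.g. from [detect_lineages()]).
#' @param ratio nearest/second-nearest centroid distance ratio threshold.
#' @param het_mult heterozygosity multiplier threshold.
#' @return data frame: id, nearest and second clusters, distance ratio,
#'   heterozygosity, logical `flagged`.
#' @export
flag_hybrid_candidates <- function(pca, x, cluster, ratio = 0.4,
                                   het_mult = 3) {
  sc <- x_scores(pca)
  cents <- aggregate(sc, list(cluster = cluster), mean)
  cm <- as.matrix(cents[, -1, drop = FALSE])
  het <- individual_heterozygosity(x)
  med_het <- tapply(het, cluster, median)
  out <- data.frame(id = x$individuals$id, nearest = NA_integer_,
                    second = NA_integer_, dist_ratio = NA_real_,
                    het = het, flagged = FALSE)
  for (i in seq_len(nrow(sc))) {
    d <- sqrt(rowSums(sweep(cm, 2, sc[i, ])^2))
    o <- order(d)
    out$nearest[i] <- cents$cluster[o[1]]
    out$second[i] <- cents$cluster[o[2]]
    out$dist_ratio[i] <- if (d[o[2]] > 0) d[o[1]] / d[o[2]] else 0
    out$flagged[i] <- out$dist_ratio[i] > ratio &&
      het[i] > het_mult * med_het[[as.character(out$nearest[i])]]
  }
  out
}
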