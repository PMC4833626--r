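## Synthetic data: genotype matrices, RAD-locus sequences, leaf outlines and
## trait tables with configurable lineage structure and ground-truth labels.
##
## Generative model (two levels): each lineage has ancestral allele
## frequencies; loci are partitioned into "pattern" classes that fix pairwise
## divergence (loci fixed for alternate alleles between lineage pairs) and a
## shared-polymorphism class whose minor-allele frequencies are drawn from a
## beta distribution common to all lineages. Within a lineage, per-site
## frequencies drift around the lineage frequency under a Balding-Nichols
## beta model with variance set by the target among-site F_ST. Individuals
## are drawn with an inbreeding coefficient Fis = 1 - 2^-t after t
## generations of selfing from a randomly mating base.

#' Configuration for the synthetic lineage generator
#'
#' @param n_lineages number of lineages (1-3 supported).
#' @param loci number of RAD loci (one primary SNP each).
#' @param n_sites number of sampling sites.
#' @param individuals matrix (`n_lineages` x `n_sites`) of individual counts;
#'   default mirrors a three-lineage, seven-site survey with group sizes
#'   5 / 94 / 29.
#' @param fixed_diff symmetric matrix (or single value for 2 lineages) of
#'   per-pair fractions of loci fixed for alternate alleles; default is
#'   calibrated from `neis_d_targets` via [calibrate_lineage_config()].
#' @param maf_shape length-2 beta shape parameters for the shared
#'   minor-allele-frequency distribution, or `NULL` for no shared
#'   polymorphism (fully monomorphic backgrounds). Default is calibrated to
#'   `he_target`.
#' @param he_target,neis_d_targets calibration targets used when `fixed_diff`
#'   or `maf_shape` are not given: a group-level expected heterozygosity and
#'   pairwise Nei's D values (vector over pairs in column order 1-2, 1-3,
#'   2-3).
#' @param selfing_generations generations of selfing from a random-mating
#'   base; controls residual heterozygosity via `Fis = 1 - 2^-t`. `Inf`
#'   forces complete homozygosity.
#' @param site_fst target Weir-Cockerham F_ST among sites within a lineage.
#' @param missing_rate_individual,missing_rate_locus mean missing-call rates;
#'   per-individual and per-locus rates are drawn from beta distributions
#'   with these means (long right tails, so occasional high-dropout
#'   individuals/loci occur).
#' @param extra_snp_fraction fraction of RAD loci carrying a second, fully
#'   linked SNP (exercises one-SNP-per-locus selection and assay-suitability
#'   rules).
#' @param hybrids list of hybrid injections, each
#'   `list(parents = c(a, b), class = "F1"|"F2"|"F3"|"BC", n = count)`.
#' @param seed integer RNG seed.
#' @return list of class `lineage_config`.
#' @export
lineage_config <- function(n_lineages = 3,
                           loci = 3928,
                           n_sites = 7,
                           individuals = NULL,
                           fixed_diff = NULL,
                           maf_shape = NULL,
                           he_target = 0.065,
                           neis_d_targets = NULL,
                           selfing_generations = 5,
                           site_fst = 0.10,
                           missing_rate_individual = 0.03,
                           missing_rate_locus = 0.02,
                           extra_snp_fraction = 0.15,
                           hybrids = list(),
                           seed = 1L) {
  if (n_lineages < 1 || n_lineages > 3)
    stop("n_lineages must be 1, 2 or 3")
  if (loci < 1 || n_sites < 1) stop("counts must be positive")
  for (r in c(site_fst, missing_rate_individual, missing_rate_locus,
              extra_snp_fraction))
    if (r < 0 || r >= 1) stop("rates and fractions must lie in [0, 1)")
  if (is.null(individuals)) {
    individuals <- switch(n_lineages,
      matrix(rep(10, n_sites), 1),
      rbind(rep_len(c(14, 13), n_sites), rep_len(c(4, 4, 5), n_sites)),
      {
        if (n_sites != 7) stop("default individuals table assumes 7 sites; supply one")
        rbind(c(0, 0, 2, 0, 0, 3, 0),
              c(11, 7, 16, 16, 6, 18, 20),
              c(0, 10, 0, 0, 9, 10, 0))
      })
  }
  individuals <- as.matrix(individuals)
  if (nrow(individuals) != n_lineages || ncol(individuals) != n_sites)
    stop("individuals must be an n_lineages x n_sites count matrix")
  if (any(individuals < 0)) stop("counts must be non-negative")

  npairs <- n_lineages * (n_lineages - 1) / 2
  if (is.null(neis_d_targets))
    neis_d_targets <- if (n_lineages == 3) c(0.65, 0.65, 0.22) else
      rep(0.22, npairs)
  no_poly <- length(maf_shape) == 1 && is.na(maf_shape)  # NA = no shared polymorphism
  if (is.null(fixed_diff) || is.null(maf_shape)) {
    group_n <- rowSums(individuals)
    w2 <- rowSums((individuals / pmax(group_n, 1))^2)
    cal <- calibrate_lineage_config(n_lineages, he_target, neis_d_targets,
                                    site_fst, n_sites,
                                    shared_polymorphism = !no_poly,
                                    group_n = pmax(group_n, 1),
                                    site_weights_sq = w2,
                                    fis = 1 - 2^-selfing_generations)
    if (is.null(fixed_diff)) fixed_diff <- cal$fixed_diff
    if (is.null(maf_shape)) maf_shape <- cal$maf_shape
  }
  if (no_poly) maf_shape <- NULL
  if (n_lineages > 1) {
    if (length(fixed_diff) == 1)
      fixed_diff <- matrix(c(0, fixed_diff, fixed_diff, 0), 2)
    fixed_diff <- as.matrix(fixed_diff)
    if (!isSymmetric(unname(fixed_diff)))
      stop("fixed_diff must be symmetric over lineage pairs")
    if (any(fixed_diff < 0 | fixed_diff > 1))
      stop("fixed_diff fractions must lie in [0, 1]")
  } else fixed_diff <- matrix(0, 1, 1)

  structure(list(n_lineages = n_lineages, loci = loci, n_sites = n_sites,
                 individuals = individuals, fixed_diff = fixed_diff,
                 maf_shape = maf_shape, he_target = he_target,
                 neis_d_targets = neis_d_targets,
                 selfing_generations = selfing_generations,
                 site_fst = site_fst,
                 missing_rate_individual = missing_rate_individual,
                 missing_rate_locus = missing_rate_locus,
                 extra_snp_fraction = extra_snp_fraction,
                 hybrids = hybrids, seed = as.integer(seed)),
            class = "lineage_config")
}

#' @export
print.lineage_config <- function(x, ...) {
  cat(sprintf("lineage_config: %d lineages, %d loci, %d sites, %d individuals\n",
              x$n_lineages, x$loci, x$n_sites, sum(x$individuals)))
  cat(sprintf("  selfing generations %s (Fis = %.3f), site F_ST %.2f, seed %d\n",
              format(x$selfing_generations), 1 - 2^-x$selfing_generations,
              x$site_fst, x$seed))
  invisible(x)
}

#' Calibrate generator parameters to diversity and distance targets
#'
#' Solves for the pairwise fixed-difference fractions and the shared
#' minor-allele-frequency beta distribution so that the generated data hit a
#' target group-level unbiased expected heterozygosity and target pairwise
#' Nei's D values in expectation. Uses the identities
#' `D = -ln(1 - f / Jx)` (a pair-diff locus moves the cross-identity term
#' from 1 to 0) and `He = x_shared * E[2pq] * (1 - F/n_sites)` (only
#' shared-pattern loci are polymorphic within a lineage; pooling drifted site
#' frequencies shrinks diversity slightly), iterated to a fixed point.
#' Infeasible target combinations (pattern fractions outside the simplex)
#' are rejected.
#'
#' @param n_lineages 2 or 3.
#' @param he_target group-level expected heterozygosity target.
#' @param neis_d_targets pairwise Nei's D targets (length 1 or 3).
#' @param site_fst,n_sites among-site drift parameters (enter the He
#'   correction).
#' @param shape1 first beta shape parameter, held fixed while the second is
#'   solved.
#' @param shared_polymorphism set `FALSE` to skip the He calibration (no
#'   shared polymorphism; backgrounds monomorphic).
#' @param group_n per-lineage total sample sizes; when supplied, the
#'   expected sampling inflation of the gene identities (`E[sum p-hat^2] =
#'   sum p^2 + 2 Var(p-hat)`) enters the Nei's D mapping, so the targets are
#'   hit by the standard (plug-in) estimator at those sample sizes.
#' @param site_weights_sq per-lineage sums of squared site sampling weights
#'   (defaults to `1/n_sites`, the equal-weight value).
#' @param fis within-site inbreeding coefficient used in the sampling
#'   variance term.
#' @return list with `fixed_diff` (matrix), `maf_shape`, `pattern_fractions`.
#' @export
calibrate_lineage_config <- function(n_lineages = 3, he_target = 0.065,
                                     neis_d_targets = c(0.65, 0.65, 0.22),
                                     site_fst = 0.10, n_sites = 7,
                                     shape1 = 0.5,
                                     shared_polymorphism = TRUE,
                                     group_n = NULL,
                                     site_weights_sq = NULL,
                                     fis = 1) {
  npairs <- n_lineages * (n_lineages - 1) / 2
  if (length(neis_d_targets) != npairs)
    stop("need one Nei's D target per lineage pair")
  if (is.null(site_weights_sq))
    site_weights_sq <- rep(1 / n_sites, n_lineages)
  w2bar <- mean(site_weights_sq)
  pair_idx <- which(lower.tri(matrix(0, n_lineages, n_lineages)),
                    arr.ind = TRUE)[, c(2, 1), drop = FALSE]
  e2pq <- 0
  f <- rep(0, npairs)
  for (it in 1:25) {
    pat <- pattern_fractions(n_lineages, f)
    S <- unname(pat["shared"])
    if (shared_polymorphism) {
      e2pq <- he_target / (S * (1 - site_fst * w2bar))
      if (e2pq >= 0.5)
        stop("infeasible calibration: required within-lineage diversity too high")
    }
    J0 <- 1 - e2pq
    infl <- if (is.null(group_n)) rep(0, n_lineages) else
      e2pq * (site_fst * site_weights_sq + (1 + fis) / (2 * group_n))
    Jx <- S * (J0 + infl) + (1 - S)
    f <- vapply(seq_len(npairs), function(k) {
      a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
      1 - S * e2pq - sqrt(Jx[a] * Jx[b]) * exp(-neis_d_targets[k])
    }, 0)
    if (any(f < 0 | f > 1))
      stop("infeasible calibration: Nei's D targets unreachable")
  }
  maf_shape <- NULL
  if (shared_polymorphism) {
    ## solve beta shape2: E[2pq] = 2ab / ((a+b)(a+b+1)), taking the root on
    ## the decreasing branch (mass concentrated near zero, as for real SNPs)
    fshape <- function(b) 2 * shape1 * b / ((shape1 + b) * (shape1 + b + 1)) - e2pq
    b_peak <- sqrt(shape1 * (shape1 + 1))
    if (fshape(b_peak) < 0)
      stop("infeasible calibration: no beta distribution with shape1 = ",
           shape1, " attains the required diversity")
    maf_shape <- c(shape1, uniroot(fshape, c(b_peak, 1e6))$root)
  }
  fd <- matrix(0, n_lineages, n_lineages)
  fd[lower.tri(fd)] <- f
  fd <- fd + t(fd)
  list(fixed_diff = fd, maf_shape = maf_shape,
       pattern_fractions = pattern_fractions(n_lineages, f))
}

## internal: solve pattern-class fractions from pairwise fixed-diff fractions.
## For 3 lineages the biallelic patterns are (up to allele labels):
##   shared  - all lineages same allele (polymorphic background)
##   d1      - lineage 1 differs from 2 and 3 (pairs 12 and 13)
##   d2      - lineage 2 differs from 1 and 3 (pairs 12 and 23)
##   d3      - lineage 3 differs from 1 and 2 (pairs 13 and 23)
## (all three pairs differing simultaneously is impossible with two alleles)
pattern_fractions <- function(n_lineages, f) {
  if (n_lineages == 1) return(c(shared = 1))
  if (n_lineages == 2) {
    if (f[1] > 1) stop("infeasible fixed-difference fraction > 1")
    return(c(shared = 1 - f[1], d1 = f[1]))
  }
  f12 <- f[1]; f13 <- f[2]; f23 <- f[3]
  d1 <- (f12 + f13 - f23) / 2
  d2 <- (f12 + f23 - f13) / 2
  d3 <- (f13 + f23 - f12) / 2
  xs <- 1 - d1 - d2 - d3
  if (min(d1, d2, d3, xs) < -1e-9)
    stop("infeasible fixed-difference fractions: pairwise targets violate the ",
         "triangle constraints for biallelic loci")
  c(shared = max(xs, 0), d1 = max(d1, 0), d2 = max(d2, 0), d3 = max(d3, 0))
}

## internal: deterministic largest-remainder apportionment of L loci
apportion <- function(fracs, L) {
  raw <- fracs * L
  base <- floor(raw)
  rem <- L - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Per-site allele frequencies under drift
#'
#' Draws one frequency vector per site around lineage frequencies under the
#' Balding-Nichols beta model `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose
#' among-site variance is `F p (1 - p)`, so the realized Weir-Cockerham
#' F_ST among sites approaches `target_fst` as loci grow. Fixed loci
#' (p of 0 or 1) stay fixed. `target_fst = 0` returns the lineage vector at
#' every site.
#'
#' @param lineage_freqs allele-frequency vector in `[0, 1]`.
#' @param n_sites number of sites (>= 2).
#' @param target_fst among-site F_ST in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return matrix, loci x sites.
#' @export
simulate_site_structure <- function(lineage_freqs, n_sites, target_fst,
                                    seed = NULL) {
  if (any(lineage_freqs < 0 | lineage_freqs > 1))
    stop("frequencies must lie in [0, 1]")
  if (n_sites < 2)
    stop("among-site structure is undefined for a single site")
  if (target_fst < 0 || target_fst >= 1)
    stop("target_fst must lie in [0, 1)")
  L <- length(lineage_freqs)
  with_seed(seed, {
    out <- matrix(rep(lineage_freqs, n_sites), L, n_sites)
    if (target_fst > 0) {
      poly <- lineage_freqs > 0 & lineage_freqs < 1
      if (any(poly)) {
        p <- lineage_freqs[poly]
        k <- (1 - target_fst) / target_fst
        draws <- matrix(rbeta(sum(poly) * n_sites,
                              rep(p * k, n_sites), rep((1 - p) * k, n_sites)),
                        sum(poly), n_sites)
        out[poly, ] <- draws
      }
    }
    out
  })
}

## internal: draw genotype dosages for a block of individuals sharing site
## frequencies. p: frequency vector (loci); n: individuals; fis: inbreeding.
draw_genotypes <- function(p, n, fis) {
  L <- length(p)
  P2 <- p^2 + p * (1 - p) * fis
  P1 <- 2 * p * (1 - p) * (1 - fis)
  u <- matrix(runif(n * L), n, L)
  m2 <- matrix(P2, n, L, byrow = TRUE)
  m1 <- matrix(P1, n, L, byrow = TRUE)
  g <- (u < m2) * 2L + (u >= m2 & u < m2 + m1) * 1L
  storage.mode(g) <- "integer"
  g
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

substitute_base <- function(seq, pos, base) {
  s <- strsplit(seq, "")[[1]]
  cur <- s[pos]
  alt <- setdiff(c("A", "C", "G", "T"), cur)
  s[pos] <- if (missing(base) || is.null(base)) sample(alt, 1) else base
  paste(s, collapse = "")
}

#' Simulate a full synthetic lineage dataset
#'
#' Generates genotypes, truth labels, RAD-locus haplotype sequences, leaf
#' outlines and a trait table under a [lineage_config()]. Hybrids listed in
#' `config$hybrids` are injected by calling [cross()] / [self_individual()]
#' on sampled parents; their leaf parameters are parent-group averages.
#'
#' @param config a [lineage_config()].
#' @param with_phenotypes generate outlines and traits too? (Genotype-only
#'   runs are faster.)
#' @return list of class `lineage_dataset`: `genotypes` (a
#'   [genotype_matrix()]), `truth` (data frame `id`, `class`, `site`;
#'   `class` is `"lineage_<k>"` or a hybrid tag like `"F1_2x3"`),
#'   `rad_sequences` (data frame `locus_id`, `ref_seq`, `alt_seq`),
#'   `outlines` (named list of closed x,y matrices), `traits` (data frame),
#'   and `config`.
#' @export
simulate_lineage_dataset <- function(config, with_phenotypes = TRUE) {
  stopifnot(inherits(config, "lineage_config"))
  cf <- config
  with_seed(cf$seed, {
    L <- cf$loci
    nl <- cf$n_lineages
    pat <- pattern_fractions(nl, cf$fixed_diff[lower.tri(cf$fixed_diff)])
    counts <- apportion(pat, L)
    pattern <- sample(rep(names(pat), counts))

    ## lineage ancestral frequencies (loci x lineages)
    P <- matrix(0, L, nl)
    shared <- pattern == "shared"
    if (any(shared) && !is.null(cf$maf_shape)) {
      p0 <- rbeta(sum(shared), cf$maf_shape[1], cf$maf_shape[2])
      ## random allele polarity so ref/alt labels carry no signal
      flip <- runif(sum(shared)) < 0.5
      p0[flip] <- 1 - p0[flip]
      P[shared, ] <- p0
    }
    for (k in seq_len(nl)) {
      dk <- pattern == paste0("d", k)
      ## lineage k carries the alternate allele at its divergence loci
      ## (random polarity swap below keeps labels symmetric)
      P[dk, k] <- 1
    }
    flip <- runif(L) < 0.5
    P[flip, ] <- 1 - P[flip, ]

    fis <- if (is.infinite(cf$selfing_generations)) 1 else
      1 - 2^(-cf$selfing_generations)

    site_names <- sprintf("S%02d", seq_len(cf$n_sites))
    geno_blocks <- list()
    meta_blocks <- list()
    for (k in seq_len(nl)) {
      site_freqs <- simulate_site_structure(P[, k], max(cf$n_sites, 2),
                                            cf$site_fst)
      for (s in seq_len(cf$n_sites)) {
        nks <- cf$individuals[k, s]
        if (nks == 0) next
        g <- draw_genotypes(site_freqs[, s], nks, fis)
        ids <- sprintf("L%d_%s_%02d", k, site_names[s], seq_len(nks))
        rownames(g) <- ids
        geno_blocks[[length(geno_blocks) + 1]] <- g
        meta_blocks[[length(meta_blocks) + 1]] <-
          data.frame(id = ids, site = site_names[s],
                     group = paste0("lineage_", k),
                     class = paste0("lineage_", k))
      }
    }
    geno <- do.call(rbind, geno_blocks)
    meta <- do.call(rbind, meta_blocks)

    ## hybrid injection
    hyb_parents <- list()
    for (hs in cf$hybrids) {
      pr <- hs$parents
      cls <- hs$class
      nh <- hs$n %||% 1
      for (j in seq_len(nh)) {
        ia <- sample(which(meta$class == paste0("lineage_", pr[1])), 1)
        ib <- sample(which(meta$class == paste0("lineage_", pr[2])), 1)
        f1 <- cross(geno[ia, ], geno[ib, ])
        ind <- switch(cls,
          F1 = f1,
          F2 = self_individual(f1),
          F3 = self_individual(self_individual(f1)),
          BC = cross(f1, geno[sample(which(meta$class ==
                       paste0("lineage_", pr[2])), 1), ]),
          stop("unknown hybrid class: ", cls))
        id <- sprintf("HYB_%s_%dx%d_%02d", cls, pr[1], pr[2],
                      length(hyb_parents) + 1)
        geno <- rbind(geno, setNames(ind, NULL))
        rownames(geno)[nrow(geno)] <- id
        meta <- rbind(meta, data.frame(
          id = id, site = meta$site[ia], group = NA_character_,
          class = sprintf("%s_%dx%d", cls, pr[1], pr[2])))
        hyb_parents[[id]] <- pr
      }
    }

    ## locus table: primary SNP per RAD locus, plus linked extra SNPs
    locus_ids <- sprintf("RL%05d", seq_len(L))
    pos1 <- sample.int(93, L, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ref1 <- sample(bases, L, replace = TRUE)
    alt1 <- vapply(ref1, function(b) sample(setdiff(bases, b), 1), "")
    loci <- data.frame(locus_id = locus_ids, snp_pos = pos1,
                       ref = ref1, alt = alt1)
    n_extra <- round(cf$extra_snp_fraction * L)
    extra_idx <- if (n_extra > 0) sort(sample.int(L, n_extra)) else integer(0)
    if (length(extra_idx)) {
      pos2 <- vapply(extra_idx, function(i)
        sample(setdiff(1:93, pos1[i]), 1), 0L)
      ref2 <- sample(bases, n_extra, replace = TRUE)
      alt2 <- vapply(ref2, function(b) sample(setdiff(bases, b), 1), "")
      loci <- rbind(loci, data.frame(locus_id = locus_ids[extra_idx],
                                     snp_pos = pos2, ref = ref2, alt = alt2))
      geno <- cbind(geno, geno[, extra_idx, drop = FALSE])  # complete linkage
      o <- order(loci$locus_id, loci$snp_pos)
      loci <- loci[o, ]
      geno <- geno[, o, drop = FALSE]
    }

    ## missingness: individual- and locus-level dropout rates with long tails
    beta_rate <- function(n, m) if (m <= 0) rep(0, n) else
      rbeta(n, 1, 1 / m - 1)
    ri <- beta_rate(nrow(geno), cf$missing_rate_individual)
    rl <- beta_rate(ncol(geno), cf$missing_rate_locus)
    pm <- outer(ri, rl, function(a, b) 1 - (1 - a) * (1 - b))
    geno[matrix(runif(length(geno)), nrow(geno)) < pm] <- NA_integer_

    gm <- genotype_matrix(geno,
                          data.frame(id = meta$id, site = meta$site,
                                     group = meta$group),
                          loci)

    ## RAD haplotype sequences: alleles differ at exactly the SNP offsets
    rad_sequences <- local({
      refs <- vapply(seq_len(L), function(i) random_seq(93), "")
      ## write the recorded ref/alt bases into the sequences
      by_locus <- split(seq_len(nrow(loci)), loci$locus_id)
      alt_seqs <- refs
      for (li in seq_len(L)) {
        rows <- by_locus[[locus_ids[li]]]
        s <- strsplit(refs[li], "")[[1]]
        s[loci$snp_pos[rows]] <- loci$ref[rows]
        refs[li] <- paste(s, collapse = "")
        s[loci$snp_pos[rows]] <- loci$alt[rows]
        alt_seqs[li] <- paste(s, collapse = "")
      }
      data.frame(locus_id = locus_ids, ref_seq = refs, alt_seq = alt_seqs)
    })

    outlines <- NULL
    traits <- NULL
    if (with_phenotypes && nl >= 1) {
      shape_par <- default_shape_params()[seq_len(min(nl, 3)), , drop = FALSE]
      lin <- rep(NA_integer_, nrow(meta))
      is_pure <- grepl("^lineage_", meta$class)
      lin[is_pure] <- as.integer(sub("lineage_", "", meta$class[is_pure]))
      ratio_mean <- shape_par$ratio_mean[pmin(lin, nrow(shape_par))]
      ratio_sd <- shape_par$ratio_sd[pmin(lin, nrow(shape_par))]
      for (id in names(hyb_parents)) {                 # parent-group average
        i <- which(meta$id == id)
        pr <- pmin(hyb_parents[[id]], nrow(shape_par))
        ratio_mean[i] <- mean(shape_par$ratio_mean[pr])
        ratio_sd[i] <- mean(shape_par$ratio_sd[pr])
      }
      ratios <- rnorm(nrow(meta), ratio_mean, ratio_sd)
      ratios <- pmax(ratios, 1.01)
      outlines <- lapply(seq_len(nrow(meta)), function(i)
        leaf_outline(ratios[i], noise_sd = 0.015, n_points = 128))
      names(outlines) <- meta$id

      tp <- default_trait_params()
      traits <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
        g <- pmin(if (is.na(lin[i])) hyb_parents[[meta$id[i]]][1] else lin[i],
                  3)
        sub <- tp[tp$group == paste0("lineage_", g), ]
        vals <- setNames(rnorm(nrow(sub), sub$mean, sub$se * sqrt(sub$n)),
                         sub$trait)
        vals[c("term_dim", "lat_dim", "pet_dim")] <-
          pmax(vals[c("term_dim", "lat_dim", "pet_dim")], 0.05)
        vals["hairs"] <- max(vals["hairs"], 0)
        data.frame(id = meta$id[i], lineage = meta$class[i], t(vals))
      }))
    }

    structure(list(genotypes = gm,
                   truth = data.frame(id = meta$id, class = meta$class,
                                      site = meta$site),
                   rad_sequences = rad_sequences,
                   pattern = setNames(pattern, locus_ids),
                   outlines = outlines, traits = traits, config = cf),
              class = "lineage_dataset")
  })
}

#' @export
print.lineage_dataset <- function(x, ...) {
  cat("Synthetic lineage dataset\n")
  print(x$genotypes)
  tb <- table(x$truth$class)
  cat("  truth classes:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Default leaf-shape parameters per lineage
#'
#' Terminal-leaflet length:width ratio means/SDs for the three hog-peanut
#' lineages (narrow-leaved, pubescent broad, and broad), used as outline
#' generator defaults. SDs are reconstructed from reported standard errors
#' assuming near-equal group sizes.
#'
#' @return data frame: group, ratio_mean, ratio_sd, noise_sd, n.
#' @export
default_shape_params <- function() {
  data.frame(group = paste0("lineage_", 1:3),
             ratio_mean = c(1.67, 1.23, 1.15),
             ratio_sd = c(0.15, 0.05, 0.05),
             noise_sd = 0.015,
             n = c(25, 26, 25))
}

#' Default leaf-trait parameters per lineage
#'
#' Means and standard errors for the four standard leaf traits of the three
#' lineages: terminal and right-lateral leaflet length:width ratios
#' (`term_dim`, `lat_dim`), terminal:lateral petiolule length ratio
#' (`pet_dim`) and abaxial hair count per 9 mm^2 (`hairs`). Group sizes are
#' assumed near-equal (25/26/25) when converting SEs to SDs.
#'
#' @return data frame: group, trait, mean, se, n.
#' @export
default_trait_params <- function() {
  data.frame(
    group = rep(paste0("lineage_", 1:3), each = 4),
    trait = rep(c("term_dim", "lat_dim", "pet_dim", "hairs"), 3),
    mean = c(1.67, 1.61, 3.83, 47.5,
             1.23, 1.38, 5.66, 84.5,
             1.15, 1.26, 4.66, 56.9),
    se = c(0.03, 0.02, 0.07, 3.3,
           0.01, 0.01, 0.13, 4.4,
           0.01, 0.01, 0.09, 2.3),
    n = rep(c(25, 26, 25), each = 4))
}
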