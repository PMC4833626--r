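test_that("complete selfing forces homozygosity; injected F1 het is exact", {
  cfg <- lineage_config(n_lineages = 2, loci = 300, n_sites = 2,
                        individuals = matrix(c(4, 4, 4, 4), 2),
                        selfing_generations = Inf,
                        missing_rate_individual = 0, missing_rate_locus = 0,
                        seed = 5)
  ds <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  expect_equal(unname(group_summary(ds$genotypes)$Ho), c(0, 0))

  # fully inbred monomorphic lineages differing at 30% of loci: an injected
  # F1 is heterozygous at exactly the fixed-difference loci
  cfg2 <- lineage_config(n_lineages = 2, loci = 1000, n_sites = 2,
                         individuals = matrix(2, 2, 2),
                         fixed_diff = 0.3, maf_shape = NA,
                         selfing_generations = Inf,
                         missing_rate_individual = 0, missing_rate_locus = 0,
                         extra_snp_fraction = 0,
                         hybrids = list(list(parents = c(1, 2), class = "F1",
                                             n = 1)),
                         seed = 6)
  ds2 <- simulate_lineage_dataset(cfg2, with_phenotypes = FALSE)
  hyb <- which(ds2$truth$class == "F1_1x2")
  expect_length(hyb, 1)
  expect_equal(individual_heterozygosity(ds2$genotypes$geno[hyb, ]), 0.3)
  # and its counting hybrid index is exactly 0.5
  fr <- allele_freqs(ds2$genotypes)
  expect_equal(hybrid_index(ds2$genotypes$geno[hyb, ], fr[, 1], fr[, 2],
                            method = "count")$h, 0.5)
})

test_that("generated diversity matches the analytic target within 3 bootstrap SE", {
  cfg <- lineage_config(n_lineages = 1, loci = 10000, n_sites = 2,
                        individuals = matrix(c(25, 25), 1),
                        neis_d_targets = numeric(0), he_target = 0.065,
                        missing_rate_individual = 0, missing_rate_locus = 0,
                        extra_snp_fraction = 0, seed = 12)
  ds <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  gs <- group_summary(ds$genotypes)
  # bootstrap-over-loci oracle for the SE of mean He
  g <- ds$genotypes$geno
  he_l <- apply(g, 2, oracle_he_unbiased)
  set.seed(1)
  boots <- replicate(200, mean(sample(he_l, length(he_l), replace = TRUE)))
  expect_lt(abs(gs$He - 0.065), 3 * sd(boots))
})

test_that("site structure hits its F_ST target and rejects degenerate input", {
  p <- rep(0.3, 500)
  same <- simulate_site_structure(p, 4, 0, seed = 2)
  expect_equal(same, matrix(0.3, 500, 4))
  expect_error(simulate_site_structure(p, 1, 0.1), "single site")
  expect_error(simulate_site_structure(p, 4, 1.2), "target_fst")
  expect_error(simulate_site_structure(c(-0.1, 0.5), 3, 0.1), "frequencies")

  # realized Weir-Cockerham F_ST among sites ~ target at 5000 loci
  set.seed(33)
  p2 <- rbeta(5000, 0.8, 2)
  fr <- simulate_site_structure(p2, 7, 0.10, seed = 9)
  # sample many diploids per site under random mating and estimate
  geno <- do.call(rbind, lapply(1:7, function(s)
    t(replicate(30, rbinom(5000, 2, fr[, s])))))
  gm <- make_gm(geno, site = rep(sprintf("S%d", 1:7), each = 30))
  est <- wc_fst(gm, rep(sprintf("S%d", 1:7), each = 30))$multilocus
  expect_lt(abs(est - 0.10), 0.02)
})

test_that("identical seeds reproduce the dataset; different seeds differ", {
  cfg <- lineage_config(loci = 150, seed = 44)
  d1 <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  d2 <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  expect_identical(d1$genotypes$geno, d2$genotypes$geno)
  cfg3 <- lineage_config(loci = 150, seed = 45)
  d3 <- simulate_lineage_dataset(cfg3, with_phenotypes = FALSE)
  expect_false(identical(d1$genotypes$geno, d3$genotypes$geno))
})

test_that("infeasible divergence targets are rejected with a message", {
  # pairwise fixed-difference fractions violating the biallelic triangle
  # constraint cannot be realized
  expect_error(simulate_lineage_dataset(
    lineage_config(n_lineages = 3,
                   loci = 50,
                   fixed_diff = matrix(c(0, .9, .9,
                                         .9, 0, .9,
                                         .9, .9, 0), 3),
                   maf_shape = c(0.5, 5)),
    with_phenotypes = FALSE), "infeasible|triangle")
  # two near-identical pairs cannot both be nearly fixed against each other
  expect_error(calibrate_lineage_config(3, neis_d_targets = c(0.1, 0.1, 3)),
               "infeasible|triangle")
  expect_error(lineage_config(missing_rate_individual = 1.2), "rates")
})

test_that("RAD sequences differ between alleles exactly at recorded SNP offsets", {
  cfg <- lineage_config(loci = 60, extra_snp_fraction = 0.3, seed = 8)
  ds <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  loci <- ds$genotypes$loci
  for (i in seq_len(nrow(ds$rad_sequences))) {
    rs <- strsplit(ds$rad_sequences$ref_seq[i], "")[[1]]
    as_ <- strsplit(ds$rad_sequences$alt_seq[i], "")[[1]]
    diffs <- which(rs != as_)
    want <- sort(loci$snp_pos[loci$locus_id == ds$rad_sequences$locus_id[i]])
    expect_identical(diffs, as.integer(want))
  }
  # every individual in the genotype matrix has a truth label
  expect_setequal(ds$truth$id, ds$genotypes$individuals$id)
})

test_that("leaf outlines are closed, labelled, and hit aspect-ratio targets", {
  # a zero-noise circle measures 1.0 within discretization error
  circ <- leaf_outline(1, noise_sd = 0, n_points = 256, asym = 0)
  expect_equal(outline_aspect_ratio(circ), 1, tolerance = 1 / 256)
  expect_error(leaf_outline(0), "degenerate")
  expect_error(leaf_outline(1, n_points = 8), "32")

  # group means reproduce the configured ratio means within 2 SE
  sp <- default_shape_params()
  sp$n <- c(40, 40, 40)
  sim <- simulate_leaf_outlines(sp, n_points = 96, seed = 21)
  measured <- vapply(sim$outlines, outline_aspect_ratio, 0)
  for (g in seq_len(3)) {
    v <- measured[sim$labels == sp$group[g]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - sp$ratio_mean[g]), 2 * se + 0.02)
  }

  # zero-noise ellipse-family outline: EFA first harmonic matches the
  # arc-length Fourier-integral oracle
  ell <- ellipse_outline(2, 1, 128)
  ef <- elliptic_fourier(ell, 4)
  orc <- oracle_efa(ell, 4, refine = 400)
  expect_equal(ef$an[1], orc$an[1], tolerance = 1e-6)
  expect_equal(ef$dn[1], orc$dn[1], tolerance = 1e-6)
})

test_that("trait tables honour their configured moments", {
  tp <- default_trait_params()
  tp0 <- tp; tp0$se <- 0
  t0 <- simulate_trait_table(tp0, n_per_group = 5, seed = 3)
  for (g in unique(tp$group))
    expect_equal(unname(unlist(t0[t0$lineage == g, "term_dim"])),
                 rep(tp$mean[tp$group == g & tp$trait == "term_dim"], 5))

  tt <- simulate_trait_table(tp, n_per_group = 200, seed = 4)
  for (g in unique(tp$group)) {
    for (tr in c("term_dim", "hairs")) {
      v <- tt[tt$lineage == g, tr]
      target <- tp$mean[tp$group == g & tp$trait == tr]
      expect_lt(abs(mean(v) - target), 2.5 * sd(v) / sqrt(length(v)))
    }
  }
  expect_true(all(tt$hairs >= 0))
  tp_much <- tp; tp_much$se <- tp$se / 10
  # near-separated classes: LOOCV is perfect
  tt2 <- simulate_trait_table(tp_much, n_per_group = 15, seed = 5)
  rep <- lda_loocv(tt2[c("term_dim", "lat_dim", "pet_dim", "hairs")],
                   tt2$lineage)
  expect_equal(rep$success_rate, 100)
})
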