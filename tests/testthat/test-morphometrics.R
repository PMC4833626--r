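test_that("EFA of a circle is a pure first harmonic", {
  circ <- ellipse_outline(1.5, 1.5, 128)
  ef <- elliptic_fourier(circ, 6)
  expect_equal(ef$an[1], 1.5, tolerance = 1e-3)
  expect_equal(ef$dn[1], 1.5, tolerance = 1e-3)
  higher <- sqrt(ef$an[-1]^2 + ef$bn[-1]^2 + ef$cn[-1]^2 + ef$dn[-1]^2)
  expect_lt(max(higher), 1e-6 * 1.5)
})

test_that("EFA matches the independent Fourier-integral oracle on an ellipse", {
  ell <- ellipse_outline(2, 1, 96)
  ef <- elliptic_fourier(ell, 5)
  orc <- oracle_efa(ell, 5, refine = 500)
  expect_equal(ef$an, orc$an, tolerance = 1e-6)
  expect_equal(ef$bn, orc$bn, tolerance = 1e-6)
  expect_equal(ef$cn, orc$cn, tolerance = 1e-6)
  expect_equal(ef$dn, orc$dn, tolerance = 1e-6)
  # after orientation normalization b1 and c1 vanish and the first-harmonic
  # ellipse is axis-aligned
  nf <- normalize_efa(ef, "orientation")
  expect_equal(nf$bn[1], 0, tolerance = 1e-9)
  expect_equal(nf$cn[1], 0, tolerance = 1e-9)
  expect_gt(nf$an[1], nf$dn[1])
})

test_that("normalized coefficients are invariant to similarity transforms", {
  set.seed(7)
  leaf <- leaf_outline(1.4, noise_sd = 0.05, n_points = 120)
  ref <- normalize_efa(elliptic_fourier(leaf, 12))
  base <- flatten_efa(ref)
  # rotation, scaling, translation
  for (ang in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    tr <- sweep(3.7 * leaf %*% R, 2, c(11, -4), `+`)
    cmp <- normalize_efa(elliptic_fourier(tr, 12))
    expect_lt(max(abs(flatten_efa(cmp) - base)), 1e-6)
  }
  # starting-point shift
  sh <- leaf[c(45:120, 1:44), ]
  cmp <- normalize_efa(elliptic_fourier(sh, 12))
  expect_lt(max(abs(flatten_efa(cmp) - base)), 1e-6)
  # reversed traversal
  cmp <- normalize_efa(elliptic_fourier(leaf[120:1, ], 12))
  expect_lt(max(abs(flatten_efa(cmp) - base)), 1e-6)
  # scale is genuinely removed in full mode
  expect_equal(ref$an[1], 1)
  # different shapes stay apart
  other <- normalize_efa(elliptic_fourier(leaf_outline(2.6, 0, 120), 12))
  expect_gt(max(abs(flatten_efa(other) - base)), 1e-3)
})

test_that("reconstruction error shrinks with harmonics; one harmonic is an ellipse", {
  set.seed(8)
  leaf <- leaf_outline(1.3, noise_sd = 0.04, n_points = 100)
  errs <- vapply(c(1, 3, 8, 25, 50), function(nh) {
    rec <- inverse_efa(elliptic_fourier(leaf, nh), 300)
    mean(dist_to_polygon(rec, leaf))
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
  diam <- max(dist(leaf[seq(1, 100, by = 4), ]))
  expect_lt(errs[length(errs)], 1e-3 * diam)

  # single-harmonic reconstruction of an ellipse is close to it (the
  # first-harmonic ellipse of the arc-length parameterization is slightly
  # rounder); adding harmonics collapses the residual
  ell <- ellipse_outline(2, 1, 64)
  e1 <- max(dist_to_polygon(inverse_efa(elliptic_fourier(ell, 1), 200), ell))
  e5 <- max(dist_to_polygon(inverse_efa(elliptic_fourier(ell, 5), 200), ell))
  expect_lt(e1, 0.25)
  expect_lt(e5, e1 / 10)

  # harmonic count is capped at the Nyquist limit with a warning
  expect_warning(elliptic_fourier(ell, 64), "capped")
})

test_that("EFA harmonic power accumulates monotonically", {
  set.seed(12)
  leaf <- leaf_outline(1.5, noise_sd = 0.06, n_points = 128)
  ef <- elliptic_fourier(leaf, 30)
  pw <- (ef$an^2 + ef$bn^2 + ef$cn^2 + ef$dn^2) / 2
  cum <- cumsum(pw)
  expect_true(all(diff(cum) >= 0))
  expect_gt(cum[5] / cum[30], 0.95)   # low harmonics dominate a smooth leaf
})

test_that("shape PCA separates aspect-ratio families", {
  set.seed(5)
  narrow <- replicate(10, leaf_outline(1.8, 0.02, 96), simplify = FALSE)
  broad <- replicate(10, leaf_outline(1.1, 0.02, 96), simplify = FALSE)
  coeffs <- lapply(c(narrow, broad), elliptic_fourier, n_harmonics = 8)
  sp <- efa_pca(coeffs, 2)
  lab <- rep(c("n", "b"), each = 10)
  expect_gt(abs(mean(sp$scores[lab == "n", 1]) -
                  mean(sp$scores[lab == "b", 1])),
            2 * max(tapply(sp$scores[, 1], lab, sd)))
  # identical outlines give zero variance
  same <- replicate(5, ellipse_outline(2, 1, 64), simplify = FALSE)
  sp0 <- efa_pca(lapply(same, elliptic_fourier, n_harmonics = 6), 2)
  expect_lt(sum(sp0$scores^2), 1e-12)
  # scores are orthogonal across components
  expect_lt(abs(cor(sp$scores[, 1], sp$scores[, 2])), 1e-6)
})

test_that("one-way ANOVA matches the two-group closed form F = t^2", {
  set.seed(3)
  y <- c(rnorm(8, 10, 1), rnorm(9, 12, 1))
  g <- rep(c("a", "b"), c(8, 9))
  res <- trait_anova(data.frame(y = y), g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$table$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$table$p, tt$p.value, tolerance = 1e-10)
  # identical group means: F small, p large
  set.seed(4)
  y2 <- rnorm(30)
  res2 <- trait_anova(data.frame(y = y2), rep(c("a", "b", "c"), 10))
  expect_gt(res2$table$p, 0.05)
  # zero within-group variance is flagged
  expect_warning(trait_anova(data.frame(y = rep(c(1, 2), each = 3)),
                             rep(c("a", "b"), each = 3)),
                 "zero within-group variance")
})

test_that("traits drawn from the default lineage parameters are strongly significant", {
  tt <- simulate_trait_table(n_per_group = 25, seed = 9)
  res <- trait_anova(tt[c("term_dim", "lat_dim", "pet_dim", "hairs")],
                     tt$lineage)
  expect_true(all(res$table$p < 0.001))
  # Tukey letters separate the divergent lineage on leaf shape
  expect_false(res$letters["term_dim", "lineage_1"] %in%
                 res$letters["term_dim", c("lineage_2", "lineage_3")])
})

test_that("LDA LOOCV: perfect separation, permutation baseline, determinism", {
  set.seed(6)
  X <- data.frame(f1 = c(rnorm(15, 0), rnorm(15, 10), rnorm(15, 20)),
                  f2 = rnorm(45))
  lab <- rep(c("a", "b", "c"), each = 15)
  rep1 <- lda_loocv(X, lab)
  expect_equal(rep1$success_rate, 100)
  expect_equal(as.vector(rowSums(rep1$confusion)), rep(15L, 3) + 0)
  rep2 <- lda_loocv(X, lab)
  expect_identical(rep1$confusion, rep2$confusion)
  # shuffled labels: near-chance accuracy for 3 balanced classes
  set.seed(61)
  rates <- replicate(10, lda_loocv(X, sample(lab))$success_rate)
  expect_lt(mean(rates), 60)
  expect_error(lda_loocv(X, rep(c("a", "b"), c(44, 1))), "single member")
})

test_that("lineage confusion concentrates in the two similar groups", {
  # synthetic leaves from the default lineage parameters: the divergent
  # narrow-leaved lineage separates; the two broad-leaved lineages confuse
  set.seed(10)
  tt <- simulate_trait_table(n_per_group = 26, seed = 10)
  sp <- default_shape_params(); sp$n <- rep(26, 3)
  out <- simulate_leaf_outlines(sp, n_points = 96, seed = 11)
  coeffs <- lapply(out$outlines, elliptic_fourier, n_harmonics = 8)
  pcs <- efa_pca(coeffs, 1)
  feats <- cbind(tt[c("term_dim", "lat_dim", "pet_dim", "hairs")],
                 lat_PC1 = pcs$scores[, 1])
  rep <- lda_loocv(feats, tt$lineage)
  cm <- rep$confusion
  err_12 <- cm["lineage_1", "lineage_2"] + cm["lineage_2", "lineage_1"] +
    cm["lineage_1", "lineage_3"] + cm["lineage_3", "lineage_1"]
  err_23 <- cm["lineage_2", "lineage_3"] + cm["lineage_3", "lineage_2"]
  expect_gte(err_23, err_12)
  expect_gt(rep$success_rate, 60)
})
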