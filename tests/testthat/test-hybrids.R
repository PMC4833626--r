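test_that("cross follows Mendelian expectations", {
  L <- 50
  expect_equal(cross(rep(2L, L), rep(2L, L)), rep(2L, L))    # AA x AA -> AA
  f1 <- cross(rep(2L, L), rep(0L, L))
  expect_equal(f1, rep(1L, L))                               # AA x aa -> Aa
  expect_equal(individual_heterozygosity(f1), 1)
  # Aa x aa: offspring heterozygous fraction ~ 0.5 +/- binomial SE
  set.seed(1)
  off <- cross(rep(1L, 10000), rep(0L, 10000))
  expect_lt(abs(mean(off == 1L) - 0.5), 3 * sqrt(0.25 / 10000))
  # missing parental call propagates
  expect_true(is.na(cross(c(1L, NA), c(1L, 1L))[2]))
  expect_error(cross(rep(1L, 3), rep(1L, 4)), "locus sets")
})

test_that("selfing segregates 1:2:1 and preserves homozygotes", {
  expect_equal(self_individual(c(0L, 2L, 0L)), c(0L, 2L, 0L))
  set.seed(2)
  off <- self_individual(rep(1L, 10000))
  tab <- tabulate(off + 1L, 3) / 10000
  # exact multinomial check: each class within 4 SE of (1/4, 1/2, 1/4)
  expect_lt(abs(tab[1] - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(tab[2] - 0.50), 4 * sqrt(0.25 / 10000))
  expect_lt(abs(tab[3] - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
  expect_equal(individual_heterozygosity(off), 0.5, tolerance = 0.02)
})

test_that("hybrid generations halve heterozygosity and spread the index", {
  pp <- inbred_pair(L = 2000, diff_frac = 0.3, n_each = 5)
  sim <- simulate_hybrid_generations(pp$A, pp$B, n_sim = 200, seed = 42,
                                     index_method = "count")
  s <- sim$summary
  # fully inbred parents differing at fraction d: F1 heterozygosity = d exactly
  expect_equal(s$mean_het[s$class == "F1"], 0.3, tolerance = 1e-12)
  expect_equal(s$mean_het[s$class == "F2"] / s$mean_het[s$class == "F1"],
               0.5, tolerance = 0.05)
  expect_equal(s$mean_het[s$class == "F3"] / s$mean_het[s$class == "F2"],
               0.5, tolerance = 0.08)
  # mean hybrid index ~ 0.5 in all classes; SD non-decreasing F1 -> F3
  expect_equal(s$mean_index, rep(0.5, 3), tolerance = 0.01)
  expect_lte(s$sd_index[1], s$sd_index[2])
  expect_lte(s$sd_index[2], s$sd_index[3])

  # determinism under a fixed seed
  sim2 <- simulate_hybrid_generations(pp$A, pp$B, n_sim = 200, seed = 42,
                                      index_method = "count")
  expect_identical(sim$sims, sim2$sims)
  expect_error(simulate_hybrid_generations(pp$A, pp$B, n_sim = 1), "n_sim")
})

test_that("hybrid index: boundaries, F1 symmetry, ML equals counting on fixed differences", {
  L <- 100
  pa <- rep(0, L); pb <- rep(1, L)
  expect_equal(hybrid_index(rep(0L, L), pa, pb)$h, 0)   # all A alleles
  expect_equal(hybrid_index(rep(2L, L), pa, pb)$h, 1)
  f1 <- rep(1L, L)
  expect_equal(hybrid_index(f1, pa, pb, method = "ml")$h, 0.5)
  expect_equal(hybrid_index(f1, pa, pb, method = "count")$h, 0.5)
  # ML equals the counting estimator exactly at fixed differences
  set.seed(8)
  g <- rbinom(L, 2, 0.65)
  hml <- hybrid_index(g, pa, pb, method = "ml")$h
  hct <- hybrid_index(g, pa, pb, method = "count")$h
  expect_equal(hml, hct, tolerance = 1e-10)
  expect_error(hybrid_index(g, pa, pa), "informative")
})

test_that("ML hybrid index recovers a known admixture proportion", {
  set.seed(14)
  L <- 5000
  g <- rbinom(L, 2, 0.7)   # h* = 0.7 on fixed-difference loci
  est <- hybrid_index(g, rep(0, L), rep(1, L))
  expect_lt(abs(est$h - 0.7), 0.02)
  expect_true(est$lower < est$h && est$h < est$upper)
  expect_lt(est$upper - est$lower, 0.05)
})

test_that("ML hybrid index agrees with the independent score-bisection oracle", {
  set.seed(9)
  for (rep in 1:5) {
    L <- 20
    pa <- runif(L, 0, 0.45); pb <- runif(L, 0.55, 1)
    g <- rbinom(L, 2, 0.4 * pb + 0.6 * pa)
    h_pkg <- hybrid_index(g, pa, pb)$h
    h_orc <- oracle_hybrid_ml(g, pa, pb)
    expect_equal(h_pkg, h_orc, tolerance = 1e-10)
  }
})

test_that("classification recovers constructed classes and flags backcrosses", {
  pp <- inbred_pair(L = 2000, diff_frac = 0.3, n_each = 6)
  sim <- simulate_hybrid_generations(pp$A, pp$B, n_sim = 300, seed = 3,
                                     index_method = "count")
  pa <- sim$freqs_a; pb <- sim$freqs_b
  # an observation at the F1 center is F1
  s1 <- sim$summary[sim$summary$class == "F1", ]
  expect_equal(classify_hybrid(s1$mean_het, 0.5, sim)$label, "F1")
  # a parental observation
  expect_equal(classify_hybrid(0, 0, sim)$label, "parental")
  expect_equal(classify_hybrid(0.001, 1, sim)$label, "parental")
  # selfed backcross must not be called F1
  set.seed(4)
  f1 <- cross(pp$A[1, ], pp$B[1, ])
  bc <- cross(f1, pp$B[2, ])
  bc_selfed <- self_individual(self_individual(bc))
  h <- hybrid_index(bc_selfed, pa, pb, method = "count")$h
  call <- classify_hybrid(individual_heterozygosity(bc_selfed), h, sim)
  expect_false(call$label == "F1")
  expect_true(call$label %in% c("backcross-like", "uncertain"))
})

test_that("frequency-based parental sampling reproduces the halving pattern", {
  pp <- inbred_pair(L = 1000, diff_frac = 0.3, n_each = 4)
  sim <- simulate_hybrid_generations(pp$A, pp$B, n_sim = 150, seed = 15,
                                     index_method = "count",
                                     parent_sampling = "frequency")
  s <- sim$summary
  expect_equal(s$mean_het[s$class == "F1"], 0.3, tolerance = 1e-12)
  expect_equal(s$mean_het[s$class == "F2"] / s$mean_het[s$class == "F1"],
               0.5, tolerance = 0.06)
})
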