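# A hand-built 3-group matrix with known diagnostic structure
diag_fixture <- function() {
  # 6 loci:
  # L1: fixed A(0) in g1, fixed alt(2) in g2+g3  -> diagnostic {1}|{2,3}
  # L2: fixed alt in g1+g2, ref in g3            -> diagnostic {1,2}|{3}
  # L3: polymorphic within g2                    -> excluded
  # L4: fixed same allele everywhere             -> excluded (no side split)
  # L5: fixed ref g1, alt g2, ref g3             -> sides {1}|{2,3} differ? no
  # L6: fixed ref in g1, alt in g2+g3            -> diagnostic {1}|{2,3}
  g1 <- rbind(c(0, 2, 0, 2, 0, 0), c(0, 2, 0, 2, 0, 0))
  g2 <- rbind(c(2, 2, 1, 2, 2, 2), c(2, 2, 0, 2, 2, 2),
              c(2, 2, 2, 2, 2, 2))
  g3 <- rbind(c(2, 0, 0, 2, 0, 2), c(2, 0, 0, 2, 0, 2))
  make_gm(rbind(g1, g2, g3),
          group = rep(c("g1", "g2", "g3"), c(2, 3, 2)),
          locus_id = paste0("R", 1:6),
          snp_pos = c(46L, 46L, 46L, 46L, 46L, 5L))
}

test_that("diagnostic loci require within-group monomorphism and a side split", {
  gm <- diag_fixture()
  cand <- find_diagnostic_loci(gm, "group", list("g1", c("g2", "g3")))
  expect_setequal(cand$locus_id, c("R1", "R6"))
  cand2 <- find_diagnostic_loci(gm, "group", list(c("g1", "g2"), "g3"))
  expect_setequal(cand2$locus_id, c("R2"))
  expect_error(find_diagnostic_loci(gm, "group", list("g1", "g2")),
               "partition")
})

test_that("panel loci coincide with per-locus F_ST = 1 between sides", {
  gm <- diag_fixture()
  cand <- find_diagnostic_loci(gm, "group", list("g1", c("g2", "g3")))
  side <- ifelse(gm$individuals$group == "g1", "s1", "s2")
  th <- wc_fst(gm, side)$per_locus
  expect_true(all(th[cand$key] == 1))
})

test_that("assay suitability enforces single variable site and flanks", {
  gm <- diag_fixture()
  cand <- find_diagnostic_loci(gm, "group", list("g1", c("g2", "g3")))
  base <- strrep("A", 45)
  seqs <- data.frame(
    locus_id = c("R1", "R6"),
    ref_seq = c(paste0(base, "C", strrep("G", 47)),       # SNP at 46, clean
                paste0("ACGT", "C", strrep("G", 88))),    # SNP at 5: short flank
    alt_seq = c(paste0(base, "T", strrep("G", 47)),
                paste0("ACGT", "T", strrep("G", 88))))
  suit <- filter_assay_suitable(cand, seqs)
  expect_identical(suit$locus_id, "R1")
  expect_equal(suit$var_pos, 46L)
  excl <- attr(suit, "excluded")
  expect_true(any(grepl("flank", excl$reason)))

  # two variable sites are rejected
  seqs2 <- seqs
  s <- strsplit(seqs2$alt_seq[1], "")[[1]]; s[70] <- "T"
  seqs2$alt_seq[1] <- paste(s, collapse = "")
  suit2 <- filter_assay_suitable(cand, seqs2)
  expect_false("R1" %in% suit2$locus_id)
  # wrong tag length is flagged
  seqs3 <- seqs
  seqs3$ref_seq[1] <- substr(seqs3$ref_seq[1], 1, 90)
  suit3 <- filter_assay_suitable(cand, seqs3)
  expect_true(any(grepl("length", attr(suit3, "excluded")$reason)))
})

test_that("panel building is deterministic with support-then-id ordering", {
  cand <- data.frame(locus_id = sprintf("R%02d", 1:10),
                     snp_pos = 40L, key = sprintf("R%02d:40", 1:10),
                     allele_side1 = "A", allele_side2 = "T",
                     dosage_side1 = 0L,
                     support = c(5, 9, 9, 2, 7, 9, 1, 3, 9, 8))
  p1 <- build_panel(cand, list("a", "b"), k = 4)
  expect_identical(p1$loci$locus_id, c("R02", "R03", "R06", "R09"))
  p2 <- build_panel(cand, list("a", "b"), k = 4)
  expect_identical(p1$loci, p2$loci)
  expect_warning(p3 <- build_panel(cand[1:2, ], list("a", "b"), k = 4),
                 "only 2")
  expect_equal(nrow(p3$loci), 2)
})

test_that("sample assignment resolves groups, conflicts and insufficiency", {
  gm <- diag_fixture()
  p1 <- build_panel(find_diagnostic_loci(gm, "group", list("g1", c("g2", "g3"))),
                    list("g1", c("g2", "g3")), k = 2)
  p2 <- build_panel(find_diagnostic_loci(gm, "group", list(c("g1", "g2"), "g3")),
                    list(c("g1", "g2"), "g3"), k = 1)
  res <- assign_samples(gm, list(p1, p2))
  expect_identical(res$label, gm$individuals$group)   # pure samples: 100%

  # mixed-signal sample: g1-specific allele at panel-1 locus (R1 ref),
  # g3-specific signal at panel-2 locus (R2 ref) -> conflict
  bad <- make_gm(rbind(c(0, 0, 0, 2, 0, 2)),
                 locus_id = paste0("R", 1:6),
                 snp_pos = c(46L, 46L, 46L, 46L, 46L, 5L))
  bad$geno[1, 6] <- 2L  # R6 says side {2,3}: hom contradiction within panel 1
  expect_identical(assign_samples(bad, list(p1, p2))$label, "conflict")

  # sample with no panel genotypes at all -> insufficient
  empty <- make_gm(matrix(NA_integer_, 1, 6),
                   locus_id = paste0("R", 1:6),
                   snp_pos = c(46L, 46L, 46L, 46L, 46L, 5L))
  expect_identical(assign_samples(empty, list(p1, p2))$label, "insufficient")

  # heterozygous panel calls are reported, never collapsed
  f1 <- make_gm(rbind(c(2, 1, 0, 2, 0, 2)),
                locus_id = paste0("R", 1:6),
                snp_pos = c(46L, 46L, 46L, 46L, 46L, 5L))
  r <- assign_samples(f1, list(p1, p2))
  expect_gt(r$het_panel_calls, 0)
  expect_true(r$label %in% c("insufficient", "g2", "g3"))
})

test_that("synthetic planted fixed differences are recovered exactly end-to-end", {
  cfg <- lineage_config(loci = 400, extra_snp_fraction = 0.2,
                        missing_rate_individual = 0.01,
                        missing_rate_locus = 0.01, seed = 27)
  ds <- simulate_lineage_dataset(cfg, with_phenotypes = FALSE)
  gm <- qc_filter(ds$genotypes)$matrix
  part <- list("lineage_1", c("lineage_2", "lineage_3"))
  cand <- find_diagnostic_loci(gm, "group", part)

  # truth: pattern "d1" loci are fixed differences between lineage 1 and the
  # rest; candidate set must contain every complete-data d1 locus and no
  # locus of a different pattern with complete data contradicting it
  pattern <- ds$pattern[cand$locus_id]
  expect_true(all(pattern == "d1"))

  suit <- filter_assay_suitable(cand, ds$rad_sequences)
  # brute-force scan of the planted sequences
  brute <- vapply(seq_len(nrow(cand)), function(i) {
    row <- ds$rad_sequences[ds$rad_sequences$locus_id == cand$locus_id[i], ]
    r <- strsplit(row$ref_seq, "")[[1]]; a <- strsplit(row$alt_seq, "")[[1]]
    diffs <- which(r != a)
    length(diffs) == 1 && diffs > 18 && diffs <= 93 - 18
  }, TRUE)
  expect_setequal(suit$locus_id, cand$locus_id[brute])

  # pure-lineage assignment never conflicts
  p1 <- build_panel(suit, part, k = min(4, nrow(suit)))
  part2 <- list(c("lineage_1", "lineage_2"), "lineage_3")
  suit2 <- filter_assay_suitable(
    find_diagnostic_loci(gm, "group", part2), ds$rad_sequences)
  p2 <- build_panel(suit2, part2, k = min(4, nrow(suit2)))
  pure <- gm[which(!is.na(gm$individuals$group)), ]
  res <- assign_samples(pure, list(p1, p2))
  expect_false(any(res$label == "conflict"))
  ok <- res$label == pure$individuals$group
  expect_true(all(ok | res$label == "insufficient"))
  expect_gt(mean(ok), 0.95)
})

test_that("majority conflict rule resolves lopsided contradictions only", {
  gm <- diag_fixture()
  p1 <- build_panel(find_diagnostic_loci(gm, "group", list("g1", c("g2", "g3"))),
                    list("g1", c("g2", "g3")), k = 2)
  p2 <- build_panel(find_diagnostic_loci(gm, "group", list(c("g1", "g2"), "g3")),
                    list(c("g1", "g2"), "g3"), k = 1)
  # R1 says g1 side, R6 says g2/g3 side: a 1-1 tie stays a conflict even
  # under the majority rule
  bad <- make_gm(rbind(c(0, 2, 0, 2, 0, 2)),
                 locus_id = paste0("R", 1:6),
                 snp_pos = c(46L, 46L, 46L, 46L, 46L, 5L))
  expect_identical(assign_samples(bad, list(p1, p2))$label, "conflict")
  expect_identical(assign_samples(bad, list(p1, p2), "majority")$label,
                   "conflict")
})
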