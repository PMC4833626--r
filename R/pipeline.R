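## Pipeline orchestration: fixed stage order qc -> popgen -> pca -> hybrid ->
## scan -> panel -> morphometrics, all randomness derived from one seed.

#' Pipeline configuration
#'
#' Collects input paths (or in-memory objects), stage toggles and stage
#' parameters. Either `genotypes` (a [genotype_matrix()] or a file path) or
#' `simulate = TRUE` (generate a synthetic dataset from `sim_config`) must be
#' supplied.
#'
#' @param genotypes a `genotype_matrix`, or a path readable by
#'   [read_genotypes()], or `NULL` when simulating.
#' @param simulate generate input data with [simulate_lineage_dataset()]?
#' @param sim_config [lineage_config()] used when simulating.
#' @param outlines named list of outline matrices (or `NULL`).
#' @param traits trait data frame with a `lineage` column (or `NULL`).
#' @param rad_sequences tag-sequence data frame for the panel stage.
#' @param stages character vector of stages to run, a subset of the default.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory, or `NULL` for no file output.
#' @param max_missing_individual,max_missing_locus QC thresholds.
#' @param n_sim hybrid simulation size.
#' @param fst_threshold divergence-island threshold.
#' @param panel_k loci per diagnostic panel.
#' @param n_harmonics elliptic Fourier harmonics.
#' @param alpha significance level for ANOVA letters and hybrid boxes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, simulate = is.null(genotypes),
                            sim_config = lineage_config(),
                            outlines = NULL, traits = NULL,
                            rad_sequences = NULL,
                            stages = c("qc", "popgen", "pca", "hybrid",
                                       "scan", "panel", "morpho"),
                            seed = 1L, outdir = NULL,
                            max_missing_individual = 0.25,
                            max_missing_locus = 0.10,
                            n_sim = 1000, fst_threshold = 0.9,
                            panel_k = 4, n_harmonics = 10, alpha = 0.05) {
  known <- c("qc", "popgen", "pca", "hybrid", "scan", "panel", "morpho")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  if (is.character(genotypes) && !file.exists(genotypes))
    stop("genotype path does not exist: ", genotypes)
  structure(list(genotypes = genotypes, simulate = simulate,
                 sim_config = sim_config, outlines = outlines,
                 traits = traits, rad_sequences = rad_sequences,
                 stages = stages, seed = as.integer(seed), outdir = outdir,
                 max_missing_individual = max_missing_individual,
                 max_missing_locus = max_missing_locus, n_sim = n_sim,
                 fst_threshold = fst_threshold, panel_k = panel_k,
                 n_harmonics = n_harmonics, alpha = alpha),
            class = "pipeline_config")
}

#' Run the lineage-discovery pipeline
#'
#' Executes the enabled stages in fixed order, passing artifacts between
#' them. Every stage draws its randomness from a seed derived from the
#' master seed, so a fixed configuration gives identical numeric output on
#' every run. A stage failure halts the run with the stage name; partial
#' results computed so far are attached to the error condition.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: per-stage summaries, `seed`,
#'   `config_hash`, and `results` (the stage artifacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  report <- list()
  results <- list()
  hash <- config_hash(cf)
  outdir <- cf$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## input
  dataset <- NULL
  gm <- if (cf$simulate) {
    cfg <- cf$sim_config
    cfg$seed <- derive_seed(cf$seed, "simulate")
    dataset <- simulate_lineage_dataset(cfg)
    if (is.null(cf$outlines)) cf$outlines <- dataset$outlines
    if (is.null(cf$traits)) cf$traits <- dataset$traits
    if (is.null(cf$rad_sequences)) cf$rad_sequences <- dataset$rad_sequences
    dataset$genotypes
  } else if (is.character(cf$genotypes)) {
    read_genotypes(cf$genotypes)
  } else cf$genotypes
  results$dataset <- dataset

  if ("qc" %in% cf$stages) {
    qc <- run_stage("qc", function()
      qc_filter(gm, cf$max_missing_individual, cf$max_missing_locus))
    gm <- qc$matrix
    results$qc <- qc
    report$qc <- list(removed_individuals = length(qc$removed_individuals),
                      removed_loci = length(qc$removed_loci),
                      snps_collapsed = qc$n_snps_collapsed,
                      n_individuals = n_individuals(gm), n_loci = n_loci(gm))
  }

  grouping <- gm$individuals$group
  has_groups <- any(!is.na(grouping))

  if ("popgen" %in% cf$stages && has_groups) {
    pg <- run_stage("popgen", function() {
      pure <- gm[which(!is.na(grouping)), ]
      list(summary = group_summary(pure, "group"),
           divergence = pairwise_divergence(pure, "group"))
    })
    results$popgen <- pg
    report$popgen <- list(groups = as.character(pg$summary$group),
                          Ho = pg$summary$Ho, He = pg$summary$He)
  }

  if ("pca" %in% cf$stages) {
    pca <- run_stage("pca", function() {
      p <- genotype_pca(gm)
      cl <- detect_lineages(p, seed = derive_seed(cf$seed, "pca"))
      list(pca = p, clusters = cl,
           candidates = flag_hybrid_candidates(p, gm, cl$cluster))
    })
    results$pca <- pca
    report$pca <- list(
      variance_fraction_pc12 = sum(pca$pca$variance_fraction[1:2]),
      n_lineage_clusters = pca$clusters$k,
      n_hybrid_candidates = sum(pca$candidates$flagged))
  }

  if ("hybrid" %in% cf$stages && has_groups) {
    hy <- run_stage("hybrid", function() {
      groups <- names(sort(table(grouping), decreasing = TRUE))
      if (length(groups) < 2) stop("need two groups for hybrid simulation")
      ga <- groups[1]; gb <- groups[2]
      sim <- simulate_hybrid_generations(
        gm[which(grouping %in% ga), ], gm[which(grouping %in% gb), ],
        n_sim = cf$n_sim, seed = derive_seed(cf$seed, "hybrid"),
        index_method = "count")
      cands <- if (!is.null(results$pca))
        results$pca$candidates$id[results$pca$candidates$flagged] else
          character(0)
      calls <- lapply(cands, function(id) {
        i <- which(gm$individuals$id == id)
        h <- hybrid_index(gm$geno[i, ], sim$freqs_a, sim$freqs_b,
                          method = "count")
        classify_hybrid(individual_heterozygosity(gm$geno[i, ]), h$h, sim,
                        alpha = cf$alpha, id = id)
      })
      list(sim = sim, calls = calls, parents = c(ga, gb))
    })
    results$hybrid <- hy
    report$hybrid <- list(parents = hy$parents,
                          n_calls = length(hy$calls),
                          labels = vapply(hy$calls, `[[`, "", "label"))
  }

  if ("scan" %in% cf$stages && has_groups && !is.null(results$popgen)) {
    sc <- run_stage("scan", function() {
      pl <- results$popgen$divergence$per_locus_fst
      dists <- lapply(pl, fst_distribution, threshold = cf$fst_threshold)
      overlaps <- list()
      if (length(pl) >= 2) {
        cmb <- utils::combn(names(pl), 2)
        for (k in seq_len(ncol(cmb)))
          overlaps[[paste(cmb[1, k], cmb[2, k], sep = " & ")]] <-
            shared_outliers(pl[[cmb[1, k]]], pl[[cmb[2, k]]],
                            cf$fst_threshold)$count
      }
      list(distributions = dists, overlaps = overlaps)
    })
    results$scan <- sc
    report$scan <- list(
      n_above = vapply(sc$distributions, `[[`, 0, "n_above"),
      u_shape = vapply(sc$distributions, u_shape_index, 0),
      overlaps = unlist(sc$overlaps))
  }

  if ("panel" %in% cf$stages && has_groups &&
      !is.null(cf$rad_sequences)) {
    pn <- run_stage("panel", function() {
      pure <- gm[which(!is.na(grouping)), ]
      groups <- sort(unique(grouping[!is.na(grouping)]))
      if (length(groups) < 2) stop("need two groups for a panel")
      parts <- if (length(groups) >= 3)
        list(list(groups[1], groups[-1]),
             list(groups[-length(groups)], groups[length(groups)])) else
        list(list(groups[1], groups[2]), list(groups[1], groups[2]))
      panels <- lapply(parts, function(pt) {
        cand <- find_diagnostic_loci(pure, "group", pt)
        suit <- filter_assay_suitable(cand, cf$rad_sequences)
        build_panel(suit, pt, cf$panel_k)
      })
      list(panels = panels, assignments = assign_samples(gm, panels))
    })
    results$panel <- pn
    report$panel <- list(
      panel_sizes = vapply(pn$panels, function(p) nrow(p$loci), 0),
      labels = table(pn$assignments$label))
  }

  if ("morpho" %in% cf$stages && !is.null(cf$outlines) &&
      !is.null(cf$traits)) {
    mo <- run_stage("morpho", function() {
      tr <- cf$traits
      pure <- grepl("^lineage_", tr$lineage)
      tr <- tr[pure, , drop = FALSE]
      coeffs <- lapply(cf$outlines[tr$id], elliptic_fourier,
                       n_harmonics = cf$n_harmonics)
      shp <- efa_pca(coeffs, n_components = 2)
      trait_cols <- intersect(c("term_dim", "lat_dim", "pet_dim", "hairs"),
                              names(tr))
      an <- trait_anova(tr[trait_cols], tr$lineage, alpha = cf$alpha)
      feats <- cbind(tr[trait_cols], lat_PC1 = shp$scores[, 1])
      ld <- lda_loocv(feats, tr$lineage)
      list(shape_pca = shp, anova = an, lda = ld)
    })
    results$morpho <- mo
    report$morpho <- list(
      anova_p = mo$anova$table$p,
      lda_success = mo$lda$success_rate,
      shape_var_pc12 = sum(mo$shape_pca$variance_fraction[1:2]))
  }

  out <- structure(list(stages = report, seed = cf$seed,
                        config_hash = hash, results = results),
                   class = "run_report")
  if (!is.null(outdir)) write_run_outputs(out, gm, outdir, hash, cf$seed)
  out
}

## internal: stable short hash of the configuration
config_hash <- function(cf) {
  scrub <- cf
  scrub$genotypes <- if (is.character(cf$genotypes)) cf$genotypes else
    !is.null(cf$genotypes)
  scrub$outlines <- length(cf$outlines)
  scrub$traits <- !is.null(cf$traits)
  scrub$rad_sequences <- !is.null(cf$rad_sequences)
  txt <- paste(deparse(scrub), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            4294967291)
}

## internal: file outputs, each named with the config hash and seed
write_run_outputs <- function(report, gm, outdir, hash, seed) {
  tag <- sprintf("%s_seed%d", hash, seed)
  write_genotypes(gm, file.path(outdir,
                                sprintf("genotypes_%s.tsv", tag)),
                  seed = seed)
  summ <- report$stages
  jsonlite::write_json(summ,
                       file.path(outdir, sprintf("summary_%s.json", tag)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  for (nm in names(x$stages)) {
    cat(sprintf("  %s:\n", nm))
    s <- x$stages[[nm]]
    for (k in names(s)) {
      v <- s[[k]]
      cat(sprintf("    %s: %s\n", k,
                  paste(format(unlist(v), digits = 3), collapse = " ")))
    }
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Thin convenience wrapper for scripted runs: reads scalar parameters and
#' file paths (relative to the YAML's directory) and builds a
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  geno <- y$genotypes
  if (!is.null(geno) && !file.exists(geno))
    geno <- file.path(base, geno)
  args <- y[setdiff(names(y), c("genotypes", "sim_config"))]
  args$genotypes <- geno
  if (!is.null(y$sim_config))
    args$sim_config <- do.call(lineage_config, y$sim_config)
  do.call(pipeline_config, args)
}
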