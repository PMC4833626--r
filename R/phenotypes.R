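## Synthetic leaf phenotypes: closed leaflet outlines from an ovoid family,
## and trait tables drawn around per-lineage means.

#' Generate a single closed leaf-like outline
#'
#' Shapes come from a smooth ovoid family: a unit radial curve
#' `rho(theta) = 1 + asym * cos(theta)` (an egg-like taper toward the tip)
#' perturbed by low-order random harmonics, then scaled anisotropically so
#' that the bounding-box length:width ratio equals `ratio` exactly (up to
#' discretization of the curve). Contours are closed and, for the default
#' noise levels, non-self-intersecting (radial curves cannot self-intersect
#' while `rho > 0`; draws violating this are rejected and redrawn).
#'
#' @param ratio target bounding-box length:width ratio (> 0).
#' @param noise_sd SD of the random harmonic perturbations.
#' @param n_points number of outline points (>= 32).
#' @param asym taper strength of the base ovoid.
#' @return matrix with columns `x`, `y`; the contour is closed implicitly
#'   (last point connects to the first).
#' @export
leaf_outline <- function(ratio, noise_sd = 0.015, n_points = 128,
                         asym = 0.18) {
  if (ratio <= 0) stop("degenerate shape: ratio must be positive")
  if (n_points < 32) stop("need at least 32 outline points")
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  for (try in 1:20) {
    rho <- 1 + asym * cos(th)
    if (noise_sd > 0) {
      for (k in 2:5) {
        amp <- rnorm(2, 0, noise_sd)
        rho <- rho + amp[1] * cos(k * th) + amp[2] * sin(k * th)
      }
    }
    if (min(rho) > 0.2) break
  }
  x <- rho * cos(th)
  y <- rho * sin(th)
  ## scale so bbox is ratio x 1 (length along x)
  x <- x / diff(range(x)) * ratio
  y <- y / diff(range(y))
  cbind(x = x, y = y)
}

#' Bounding-box aspect ratio of an outline
#'
#' @param outline matrix with columns x, y.
#' @return length:width ratio (x-extent over y-extent).
#' @export
outline_aspect_ratio <- function(outline) {
  diff(range(outline[, 1])) / diff(range(outline[, 2]))
}

#' Simulate labelled leaf outlines per group
#'
#' Per-individual aspect ratios are drawn from each group's normal
#' distribution; outlines are generated with [leaf_outline()].
#'
#' @param group_shape_params data frame with columns `group`, `ratio_mean`,
#'   `ratio_sd`, `noise_sd` and `n` (individuals per group); see
#'   [default_shape_params()].
#' @param n_points points per outline (>= 32).
#' @param seed optional RNG seed.
#' @return list with `outlines` (named list of x,y matrices), `labels`
#'   (group per outline) and `ratios` (the drawn per-individual targets).
#' @export
simulate_leaf_outlines <- function(group_shape_params = default_shape_params(),
                                   n_points = 128, seed = NULL) {
  gp <- group_shape_params
  if (any(gp$ratio_mean <= 0)) stop("degenerate parameters: ratios must be > 0")
  if (n_points < 32) stop("need at least 32 outline points")
  with_seed(seed, {
    outlines <- list()
    labels <- character(0)
    ratios <- numeric(0)
    for (r in seq_len(nrow(gp))) {
      for (j in seq_len(gp$n[r])) {
        ratio <- max(rnorm(1, gp$ratio_mean[r], gp$ratio_sd[r]), 0.2)
        id <- sprintf("%s_%03d", gp$group[r], j)
        outlines[[id]] <- leaf_outline(ratio, gp$noise_sd[r], n_points)
        labels[id] <- gp$group[r]
        ratios[id] <- ratio
      }
    }
    list(outlines = outlines, labels = labels, ratios = ratios)
  })
}

#' Simulate a per-individual trait table
#'
#' Normal draws per trait around group means, with SDs reconstructed from
#' standard errors as `se * sqrt(n)`. Hair counts are non-negative: truncated
#' normal by default, or Poisson with the group mean (`hairs_model =
#' "poisson"`). Dimension ratios are floored slightly above zero.
#'
#' @param group_trait_params data frame with columns `group`, `trait`,
#'   `mean`, `se`, `n`; see [default_trait_params()].
#' @param n_per_group individuals per group (single value or vector named by
#'   group); defaults to the `n` column.
#' @param seed optional RNG seed.
#' @param hairs_model `"truncnorm"` (default) or `"poisson"`.
#' @return data frame of class `trait_table`: `id`, `lineage`, one column per
#'   trait.
#' @export
simulate_trait_table <- function(group_trait_params = default_trait_params(),
                                 n_per_group = NULL, seed = NULL,
                                 hairs_model = c("truncnorm", "poisson")) {
  hairs_model <- match.arg(hairs_model)
  tp <- group_trait_params
  groups <- unique(tp$group)
  if (is.null(n_per_group))
    n_per_group <- setNames(vapply(groups, function(g)
      tp$n[tp$group == g][1], 0), groups)
  if (length(n_per_group) == 1)
    n_per_group <- setNames(rep(n_per_group, length(groups)), groups)
  with_seed(seed, {
    rows <- list()
    for (g in groups) {
      sub <- tp[tp$group == g, ]
      ng <- n_per_group[[g]]
      vals <- sapply(seq_len(nrow(sub)), function(r) {
        m <- sub$mean[r]; s <- sub$se[r] * sqrt(sub$n[r])
        if (sub$trait[r] == "hairs") {
          if (hairs_model == "poisson") rpois(ng, m)
          else {            # truncated-at-zero normal by rejection
            v <- rnorm(ng, m, s)
            while (any(v < 0)) v[v < 0] <- rnorm(sum(v < 0), m, s)
            v
          }
        } else pmax(rnorm(ng, m, s), 0.05)
      })
      vals <- matrix(vals, nrow = ng,
                     dimnames = list(NULL, sub$trait))
      rows[[g]] <- data.frame(id = sprintf("%s_%03d", g, seq_len(ng)),
                              lineage = g, vals)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("trait_table", "data.frame")
    out
  })
}
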