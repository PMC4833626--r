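## Leaf morphometrics: elliptic Fourier analysis of closed outlines
## (Kuhl-Giardina chain formulation over the closed polygon, arc-length
## parameterized), coefficient PCA, trait ANOVA with Tukey groupings, and
## cross-validated linear discriminant analysis.

## internal: closed-polygon increments, dropping zero-length segments
outline_increments <- function(outline) {
  xy <- as.matrix(outline)
  if (ncol(xy) != 2 || nrow(xy) < 3) stop("outline must be an n x 2 matrix")
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  if (sum(keep) < 3) stop("degenerate (zero-length) contour")
  list(dx = dx[keep], dy = dy[keep], dt = dt[keep],
       x0 = xy[1, 1], y0 = xy[1, 2])
}

signed_area <- function(outline) {
  x <- outline[, 1]; y <- outline[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes harmonic coefficient quadruples `(a_n, b_n, c_n, d_n)` plus
#' offsets `(A0, C0)` for a closed polygonal contour under arc-length
#' parameterization. Traversal direction is canonicalized to
#' counterclockwise (positive signed area) before decomposition, so reversed
#' traces of the same shape give identical coefficients.
#'
#' @param outline matrix with columns x, y; closed implicitly.
#' @param n_harmonics harmonics to compute; capped at `floor(points / 2)`
#'   (the outline's Nyquist limit) with a warning.
#' @return list of class `efa`: `an`, `bn`, `cn`, `dn` (length
#'   `n_harmonics`), `A0`, `C0`, `n_harmonics`, `normalized = FALSE`.
#' @export
elliptic_fourier <- function(outline, n_harmonics = 10) {
  xy <- as.matrix(outline)
  if (signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  inc <- outline_increments(xy)
  n_max <- floor(nrow(xy) / 2)
  if (n_harmonics > n_max) {
    warning(sprintf("n_harmonics capped at %d (outline has %d points)",
                    n_max, nrow(xy)))
    n_harmonics <- n_max
  }
  t1 <- cumsum(inc$dt)
  t0 <- c(0, t1[-length(t1)])
  Tt <- t1[length(t1)]
  an <- bn <- cn <- dn <- numeric(n_harmonics)
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / Tt
    cosd <- cos(w * t1) - cos(w * t0)
    sind <- sin(w * t1) - sin(w * t0)
    k <- Tt / (2 * pi^2 * n^2)
    an[n] <- k * sum(inc$dx / inc$dt * cosd)
    bn[n] <- k * sum(inc$dx / inc$dt * sind)
    cn[n] <- k * sum(inc$dy / inc$dt * cosd)
    dn[n] <- k * sum(inc$dy / inc$dt * sind)
  }
  ## offsets: exact integrals of the piecewise-linear contour over arc length
  delta_x <- c(0, cumsum(inc$dx)[-length(inc$dx)])
  delta_y <- c(0, cumsum(inc$dy)[-length(inc$dy)])
  A0 <- inc$x0 + sum(inc$dx / (2 * inc$dt) * (t1^2 - t0^2) +
                       (delta_x - inc$dx / inc$dt * t0) * (t1 - t0)) / Tt
  C0 <- inc$y0 + sum(inc$dy / (2 * inc$dt) * (t1^2 - t0^2) +
                       (delta_y - inc$dy / inc$dt * t0) * (t1 - t0)) / Tt
  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 n_harmonics = n_harmonics, normalized = FALSE),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("elliptic Fourier coefficients: %d harmonics%s\n",
              x$n_harmonics,
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  harmonic 1: a=%.4g b=%.4g c=%.4g d=%.4g\n",
              x$an[1], x$bn[1], x$cn[1], x$dn[1]))
  invisible(x)
}

## internal: apply a starting-point rotation theta and an orientation
## rotation psi to a coefficient set
rotate_efa <- function(cf, theta, psi) {
  n <- seq_len(cf$n_harmonics)
  co <- cos(psi); si <- sin(psi)
  out <- cf
  for (i in n) {
    M <- matrix(c(cf$an[i], cf$bn[i], cf$cn[i], cf$dn[i]), 2, byrow = TRUE)
    S <- matrix(c(cos(i * theta), -sin(i * theta),
                  sin(i * theta), cos(i * theta)), 2, byrow = TRUE)
    R <- matrix(c(co, si, -si, co), 2, byrow = TRUE)
    M2 <- R %*% M %*% S
    out$an[i] <- M2[1, 1]; out$bn[i] <- M2[1, 2]
    out$cn[i] <- M2[2, 1]; out$dn[i] <- M2[2, 2]
  }
  out
}

#' Normalize elliptic Fourier coefficients
#'
#' Removes the nuisance parameters of an outline trace: translation (offsets
#' dropped), starting point along the contour, and rotation in the plane,
#' using the first-harmonic ellipse as reference; `mode = "full"` also
#' divides by the first-harmonic semi-major axis length, removing size. After
#' normalization the first harmonic is in standard position: `a1 > 0`,
#' `c1 = 0`, `b1 ~ 0`. The two-fold ambiguity of the first-harmonic ellipse
#' (start point shifted half a period) is resolved deterministically by
#' lexicographic comparison of the candidate coefficient vectors, so any
#' rotated/scaled/shifted trace of a shape maps to the same canonical form.
#'
#' @param coeffs an `efa` object.
#' @param mode `"full"` (translation + start + rotation + scale) or
#'   `"orientation"` (no scaling; sizes retained).
#' @return normalized `efa` object (`normalized = TRUE`, `mode` recorded).
#' @export
normalize_efa <- function(coeffs, mode = c("full", "orientation")) {
  mode <- match.arg(mode)
  cf <- coeffs
  a1 <- cf$an[1]; b1 <- cf$bn[1]; c1 <- cf$cn[1]; d1 <- cf$dn[1]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-300)
    stop("zero first harmonic; cannot normalize")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  cand <- lapply(c(theta, theta + pi), function(th) {
    tmp <- rotate_efa(cf, th, 0)
    psi <- atan2(tmp$cn[1], tmp$an[1])
    out <- rotate_efa(cf, th, psi)
    if (mode == "full") {
      scale <- sqrt(out$an[1]^2 + out$cn[1]^2)
      for (f in c("an", "bn", "cn", "dn")) out[[f]] <- out[[f]] / scale
    }
    out
  })
  key <- function(cf2) round(c(cf2$an, cf2$bn, cf2$cn, cf2$dn), 9)
  pick <- if (vec_greater(key(cand[[1]]), key(cand[[2]])))
    cand[[1]] else cand[[2]]
  pick$A0 <- 0; pick$C0 <- 0
  pick$normalized <- TRUE
  pick$mode <- mode
  pick
}

## internal: lexicographic > on numeric vectors
vec_greater <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (!length(i)) return(TRUE)
  d[i[1]] > 0
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' @param coeffs an `efa` object.
#' @param n_points points on the reconstructed contour.
#' @return matrix with columns x, y.
#' @export
inverse_efa <- function(coeffs, n_points = 128) {
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  x <- rep(coeffs$A0, n_points)
  y <- rep(coeffs$C0, n_points)
  for (n in seq_len(coeffs$n_harmonics)) {
    x <- x + coeffs$an[n] * cos(n * t) + coeffs$bn[n] * sin(n * t)
    y <- y + coeffs$cn[n] * cos(n * t) + coeffs$dn[n] * sin(n * t)
  }
  cbind(x = x, y = y)
}

#' PCA of normalized elliptic Fourier coefficients
#'
#' Stacks coefficient quadruples across outlines (normalizing first if
#' needed) and runs a centered PCA, the standard route to shape spaces.
#'
#' @param coeff_list list of `efa` objects on the same harmonic count.
#' @param n_components axes to retain.
#' @param mode normalization mode passed to [normalize_efa()] for any
#'   unnormalized members.
#' @return list of class `efa_pca`: `scores`, `variance_fraction`, `rotation`,
#'   `center`, `n_harmonics`.
#' @export
efa_pca <- function(coeff_list, n_components = 2, mode = "full") {
  if (length(coeff_list) < 3) stop("need at least 3 outlines")
  nh <- unique(vapply(coeff_list, function(cf) cf$n_harmonics, 0))
  if (length(nh) != 1) stop("outlines decomposed at different harmonic counts")
  M <- t(vapply(coeff_list, function(cf) {
    if (!cf$normalized) cf <- normalize_efa(cf, mode)
    c(cf$an, cf$bn, cf$cn, cf$dn)
  }, numeric(4 * nh)))
  if (n_components > nrow(M) - 1)
    stop("fewer outlines than requested components")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  vf <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf[seq_len(k)],
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, n_harmonics = nh),
            class = "efa_pca")
}

#' One-way trait ANOVA with Tukey groupings
#'
#' Fixed-effects one-way ANOVA per trait, with Tukey HSD pairwise contrasts
#' (Tukey-Kramer under unbalance, the [stats::TukeyHSD()] behaviour) and
#' compact letter groupings at `alpha`.
#'
#' @param traits data frame of numeric traits (one column per trait).
#' @param labels group labels, one per row.
#' @param alpha significance level for the letter display.
#' @return list of class `trait_anova`: `table` (per trait: `MS` between
#'   groups, `F`, `p`), `letters` (trait x group letter matrix), `tukey`
#'   (raw Tukey results), `group_means`, `group_se`.
#' @export
trait_anova <- function(traits, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("need at least two individuals per group")
  res <- data.frame(trait = names(traits), MS = NA_real_, F = NA_real_,
                    p = NA_real_)
  letters <- matrix(NA_character_, nrow = ncol(traits),
                    ncol = nlevels(labels),
                    dimnames = list(names(traits), levels(labels)))
  tuk <- list()
  gm <- gse <- letters
  for (j in seq_along(traits)) {
    y <- traits[[j]]
    within_var <- tapply(y, labels, var)
    if (all(within_var == 0, na.rm = TRUE)) {
      warning(sprintf("trait %s has zero within-group variance; F undefined",
                      names(traits)[j]))
      next
    }
    fit <- aov(y ~ labels)
    at <- summary(fit)[[1]]
    res$MS[j] <- at["labels", "Mean Sq"]
    res$F[j] <- at["labels", "F value"]
    res$p[j] <- at["labels", "Pr(>F)"]
    th <- TukeyHSD(fit, conf.level = 1 - alpha)$labels
    tuk[[names(traits)[j]]] <- th
    letters[j, ] <- tukey_letters(rownames(th), th[, "p adj"],
                                  levels(labels), alpha)
    gm[j, ] <- sprintf("%.4g", tapply(y, labels, mean))
    gse[j, ] <- sprintf("%.2g", tapply(y, labels, function(v)
      sd(v) / sqrt(length(v))))
  }
  structure(list(table = res, letters = letters, tukey = tuk,
                 group_means = gm, group_se = gse, alpha = alpha),
            class = "trait_anova")
}

## internal: compact letter display by the insertion algorithm
tukey_letters <- function(pair_names, p_adj, groups, alpha) {
  k <- length(groups)
  diff_mat <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_along(pair_names)) {
    gs <- strsplit(pair_names[i], "-", fixed = TRUE)[[1]]
    if (p_adj[i] < alpha) {
      diff_mat[gs[1], gs[2]] <- diff_mat[gs[2], gs[1]] <- TRUE
    }
  }
  sets <- list(groups[1])
  for (g in groups[-1]) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(diff_mat[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  out <- setNames(rep("", k), groups)
  for (s in seq_along(sets))
    for (g in sets[[s]])
      out[g] <- paste0(out[g], letters[s])
  out
}

#' @export
print.trait_anova <- function(x, ...) {
  cat("One-way ANOVA by lineage\n")
  tb <- x$table
  tb$sig <- ifelse(is.na(tb$p), "", ifelse(tb$p < 0.001, "***",
              ifelse(tb$p < 0.01, "**", ifelse(tb$p < 0.05, "*", ""))))
  print.data.frame(format(tb, digits = 4), row.names = FALSE)
  cat("Tukey letter groupings (alpha =", x$alpha, "):\n")
  disp <- matrix(paste0(x$group_means, " (", x$group_se, ")", " ",
                        x$letters),
                 nrow = nrow(x$letters), dimnames = dimnames(x$letters))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Refits the discriminant `n` times, each fit excluding one sample and
#' predicting it, the standard check of how well lineage can be predicted
#' from leaf characters. Features are standardized to unit variance by
#' default; priors are proportional to class frequencies.
#'
#' @param features data frame of numeric predictors (complete cases
#'   required).
#' @param labels class labels.
#' @param standardize scale features to unit variance first?
#' @return list of class `lda_report`: `confusion` (truth x predicted),
#'   `success_rate` (percent), `per_class` (percent correct per class),
#'   `predicted`.
#' @export
lda_loocv <- function(features, labels, standardize = TRUE) {
  X <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (any(table(labels) < 2))
    stop("classes with a single member cannot be cross-validated")
  if (any(!complete.cases(X))) stop("features must be complete-case")
  if (standardize) X <- scale(X)
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- MASS::lda(X[-i, , drop = FALSE], grouping = labels[-i])
    pred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  pred <- factor(pred, levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)
  success <- 100 * sum(diag(confusion)) / n
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, success_rate = success,
                 per_class = per_class, predicted = pred),
            class = "lda_report")
}

#' @export
print.lda_report <- function(x, ...) {
  cat(sprintf("LDA leave-one-out cross-validation: %.1f%% correct\n",
              x$success_rate))
  print(x$confusion)
  invisible(x)
}
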