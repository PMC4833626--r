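# Independent brute-force oracles, written against the defining formulas
# with explicit loops; they deliberately share no code with the package.

# Weir-Cockerham per-locus theta from the variance components, one locus.
# geno: dosage vector; pop: labels.
oracle_wc_theta_locus <- function(geno, pop) {
  pop <- as.character(pop)
  pops <- unique(pop[!is.na(geno)])
  r <- length(pops)
  if (r < 2) return(NA_real_)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    g <- geno[pop == pops[k]]
    g <- g[!is.na(g)]
    n_i[k] <- length(g)
    p_i[k] <- sum(g) / (2 * length(g))
    h_i[k] <- mean(g == 1)
  }
  nbar <- mean(n_i)
  if (nbar <= 1) return(NA_real_)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  hbar <- sum(n_i * h_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

oracle_wc_components <- function(geno_mat, pop) {
  A <- D <- 0
  for (l in seq_len(ncol(geno_mat))) {
    g <- geno_mat[, l]
    pops <- unique(pop[!is.na(g)])
    if (length(pops) < 2) next
    th <- oracle_wc_theta_locus(g, pop)
    if (is.na(th)) next
    # recompute a and a+b+c via the same loop (theta = a / denom)
    pop2 <- as.character(pop)
    r <- length(pops)
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      gk <- g[pop2 == pops[k]]
      gk <- gk[!is.na(gk)]
      n_i[k] <- length(gk); p_i[k] <- sum(gk) / (2 * length(gk))
      h_i[k] <- mean(gk == 1)
    }
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    pbar <- sum(n_i * p_i) / sum(n_i)
    hbar <- sum(n_i * h_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; D <- D + a + b + cc
  }
  A / D
}

# Nei (1972) standard distance by direct evaluation of the J sums
oracle_neis_d <- function(p_a, p_b) {
  jx <- jy <- jxy <- 0
  L <- 0
  for (l in seq_along(p_a)) {
    if (is.na(p_a[l]) || is.na(p_b[l])) next
    L <- L + 1
    jx <- jx + p_a[l]^2 + (1 - p_a[l])^2
    jy <- jy + p_b[l]^2 + (1 - p_b[l])^2
    jxy <- jxy + p_a[l] * p_b[l] + (1 - p_a[l]) * (1 - p_b[l])
  }
  unname(-log((jxy / L) / sqrt((jx / L) * (jy / L))))
}

# Unbiased gene diversity, one locus, from genotype counts
oracle_he_unbiased <- function(geno) {
  g <- geno[!is.na(geno)]
  n <- length(g)
  p <- sum(g) / (2 * n)
  ho <- mean(g == 1)
  (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
}

# ML hybrid index: bisection on the analytic score function, coded
# independently (allele-level factorization of the likelihood).
oracle_hybrid_ml <- function(geno, p_a, p_b, tol = 1e-14) {
  keep <- !is.na(geno) & p_a != p_b
  g <- geno[keep]; pa <- p_a[keep]; pb <- p_b[keep]
  score <- function(h) {
    s <- 0
    for (l in seq_along(g)) {
      q <- min(max(pa[l] + h * (pb[l] - pa[l]), 1e-12), 1 - 1e-12)
      s <- s + (pb[l] - pa[l]) * (g[l] / q - (2 - g[l]) / (1 - q))
    }
    s
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  if (score(lo) <= 0) return(0)
  if (score(hi) >= 0) return(1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Elliptic Fourier coefficients by direct numerical integration of the
# arc-length parameterized contour (composite midpoint rule on a dense
# refinement of each polygon edge).
oracle_efa <- function(outline, n_harmonics, refine = 200) {
  xy <- as.matrix(outline)
  if (oracle_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  P <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  keep <- seg > 0
  Tt <- sum(seg)
  t_start <- cumsum(c(0, seg[-length(seg)]))
  an <- bn <- cn <- dn <- numeric(n_harmonics)
  for (i in which(keep)) {
    u <- (seq_len(refine) - 0.5) / refine
    t_mid <- t_start[i] + u * seg[i]
    x_mid <- P[i, 1] + u * (P[i + 1, 1] - P[i, 1])
    y_mid <- P[i, 2] + u * (P[i + 1, 2] - P[i, 2])
    w <- seg[i] / refine
    for (n in seq_len(n_harmonics)) {
      cosv <- cos(2 * pi * n * t_mid / Tt)
      sinv <- sin(2 * pi * n * t_mid / Tt)
      an[n] <- an[n] + (2 / Tt) * sum(x_mid * cosv) * w
      bn[n] <- bn[n] + (2 / Tt) * sum(x_mid * sinv) * w
      cn[n] <- cn[n] + (2 / Tt) * sum(y_mid * cosv) * w
      dn[n] <- dn[n] + (2 / Tt) * sum(y_mid * sinv) * w
    }
  }
  list(an = an, bn = bn, cn = cn, dn = dn)
}

oracle_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# minimum distance from points to a closed polygon (point-to-curve)
dist_to_polygon <- function(pts, poly) {
  P <- rbind(poly, poly[1, ])
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    dmin <- Inf
    for (j in seq_len(nrow(P) - 1)) {
      a <- P[j, ]; b <- P[j + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(max(t, 0), 1)
      d <- sqrt(sum((p - (a + t * ab))^2))
      if (d < dmin) dmin <- d
    }
    dmin
  }, 0)
}
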