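# Small fixture builders used across test files.

make_gm <- function(geno, site = "S1", group = NULL,
                    locus_id = NULL, snp_pos = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); L <- ncol(geno)
  if (is.null(locus_id)) locus_id <- sprintf("L%03d", seq_len(L))
  if (is.null(snp_pos)) snp_pos <- rep(10L, L)
  genotype_matrix(
    geno,
    data.frame(id = sprintf("ind%02d", seq_len(n)),
               site = rep_len(site, n),
               group = if (is.null(group)) NA_character_ else
                 rep_len(group, n)),
    data.frame(locus_id = locus_id, snp_pos = snp_pos,
               ref = rep_len(c("A", "C"), L), alt = rep_len(c("G", "T"), L)))
}

random_gm <- function(n = 10, L = 100, miss = 0.1, groups = c("A", "B"),
                      seed = 1) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  geno[matrix(runif(n * L) < miss, n, L)] <- NA
  make_gm(geno, group = rep_len(groups, n))
}

# two fully inbred parental pools differing at a fixed fraction of loci
inbred_pair <- function(L = 1000, diff_frac = 0.3, n_each = 10) {
  nd <- round(L * diff_frac)
  a <- matrix(0L, n_each, L)
  b <- matrix(0L, n_each, L)
  if (nd > 0) b[, seq_len(nd)] <- 2L
  list(A = a, B = b, n_diff = nd)
}

ellipse_outline <- function(a = 2, b = 1, n = 128, rot = 0, shift = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  sweep(xy %*% R, 2, shift, `+`)
}

flatten_efa <- function(cf) c(cf$an, cf$bn, cf$cn, cf$dn)
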