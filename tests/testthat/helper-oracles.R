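# Independent brute-force oracles used by the equivalence tests. These stay
# deliberately naive (loops, enumeration, grid search) and share no code
# with the implementation they check.

# all permutations of a vector, by recursive insertion
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# LMG by literal averaging of sequential R^2 gains over every ordering
lmg_bruteforce <- function(y, X) {
  p <- ncol(X)
  r2 <- function(idx) {
    if (!length(idx)) return(0)
    summary(stats::lm(y ~ X[, idx, drop = FALSE]))$r.squared
  }
  shares <- numeric(p)
  perms <- all_perms(seq_len(p))
  for (ord in perms) {
    for (j in seq_along(ord)) {
      prev <- if (j == 1) integer(0) else ord[seq_len(j - 1)]
      shares[ord[j]] <- shares[ord[j]] + (r2(c(prev, ord[j])) - r2(prev))
    }
  }
  shares / length(perms)
}

# MA slope by minimising summed squared perpendicular distances over a fine
# angle grid (lines through the centroid)
ma_slope_gridsearch <- function(x, y, n_angles = 20000) {
  xc <- x - mean(x); yc <- y - mean(y)
  angles <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = n_angles)
  perp_ss <- vapply(angles, function(a) {
    # distance of (xc, yc) from the line at angle a: |sin(a) x - cos(a) y|
    sum((sin(a) * xc - cos(a) * yc)^2)
  }, numeric(1))
  tan(angles[which.min(perp_ss)])
}

# Otsu by exhaustive search: every candidate cut between histogram bins,
# between-class variance computed from first principles on the raw values
otsu_bruteforce <- function(v, nbins = 256) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = nbins + 1)
  cand <- breaks[2:nbins]
  bcv <- vapply(cand, function(thr) {
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# match rows of A to rows of B by the best permutation (small k only);
# returns the permuted A and the total distance
match_archetypes <- function(A, B) {
  k <- nrow(A)
  best <- NULL
  for (p in all_perms(seq_len(k))) {
    d <- sum((A[p, , drop = FALSE] - B)^2)
    if (is.null(best) || d < best$d) best <- list(d = d, perm = p)
  }
  list(matched = A[best$perm, , drop = FALSE], dist = best$d)
}

# shoelace polygon area for the kite reconstruction property
shoelace_area <- function(xs, ys) {
  n <- length(xs)
  j <- c(n, seq_len(n - 1))
  abs(sum(xs[j] * ys - xs * ys[j])) / 2
}
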