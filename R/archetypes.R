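#' Archetypal analysis by alternating constrained least squares
#'
#' Approximates the rows of `X` (n x d) as convex combinations of `k`
#' archetypes that are themselves convex combinations of data points:
#' minimise `||X - A Z||_F^2` with `Z = B X`, the rows of `A` (n x k) and
#' `B` (k x n) constrained to the probability simplex. The simplex-constrained
#' least-squares subproblems are solved by nonnegative least squares
#' (`pracma::lsqnonneg`) with a sum-to-one penalty augmentation. Each restart
#' initialises `B` from `k` data points chosen by a seeded furthest-point
#' heuristic; the best of `nrep` restarts is returned.
#'
#' In the canonical canopy-form use, `X` holds the two shape ratios from
#' [shape_ratios()] and `k = 4`.
#'
#' @param X numeric matrix or data.frame, n x d, finite
#' @param k number of archetypes, `1 <= k < n`
#' @param nrep random restarts (default 5)
#' @param seed RNG seed (default 7)
#' @param max_iter maximum alternating iterations (default 500)
#' @param tol relative rss-change convergence tolerance (default 1e-8)
#' @return object of class `archetype_solution`: list with `archetypes`
#'   (k x d matrix `Z`), `weights` (n x k matrix `A`), `rss`, `k`,
#'   `converged`, `n_restarts`, `seed`
#' @export
archetypal_analysis <- function(X, k, nrep = 5, seed = 7L, max_iter = 500,
                                tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_bad("X", "must be finite")
  n <- nrow(X)
  if (k < 1 || k >= n) stop_bad("k", "need 1 <= k < n")

  best <- NULL
  for (rep_i in seq_len(nrep)) {
    set.seed(derive_seed(seed, rep_i))
    sol <- aa_single(X, k, max_iter, tol)
    if (is.null(best) || sol$rss < best$rss) best <- sol
  }
  best$n_restarts <- nrep
  best$seed <- seed
  class(best) <- "archetype_solution"
  best
}

#' @export
print.archetype_solution <- function(x, ...) {
  cat(sprintf("archetypal analysis: k=%d, rss=%.6g, converged=%s (%d restarts)\n",
              x$k, x$rss, x$converged, x$n_restarts))
  print(round(x$archetypes, 4))
  invisible(x)
}

# one ALS run from a furthest-point initialisation
aa_single <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      idx[j] <- which.max(d2)
      d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  B <- matrix(0, k, n)
  B[cbind(seq_len(k), idx)] <- 1
  Z <- B %*% X
  GX <- X %*% t(X)                     # reused by every B-step

  rss <- Inf
  converged <- FALSE
  best <- NULL
  n_worse <- 0L
  for (it in seq_len(max_iter)) {
    A <- simplex_project(Z, X)         # rows of A: X[i,] ~ A[i,] %*% Z
    # unconstrained optimal archetypes given A, then map back to the data hull
    Zstar <- tryCatch(qr.solve(crossprod(A), crossprod(A, X)),
                      error = function(e) Z)
    B <- simplex_ls(X, Zstar, gram = GX)  # rows of B: Zstar[j,] ~ B[j,] %*% X
    Z <- B %*% X
    new_rss <- sum((X - A %*% Z)^2)
    if (is.null(best) || new_rss < best$rss) {
      best <- list(archetypes = Z, weights = A, rss = new_rss)
      n_worse <- 0L
    } else {
      n_worse <- n_worse + 1L
    }
    if (is.finite(rss) && abs(rss - new_rss) <= tol * max(rss, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    # the alternating step is not strictly monotone; a sustained failure to
    # improve on the incumbent means the optimum has been reached
    if (n_worse >= 10L) {
      converged <- TRUE
      break
    }
    rss <- new_rss
  }
  c(best, list(k = k, converged = converged))
}

# Lawson-Hanson nonnegative least squares in normal-equation form:
# min ||C x - d||, x >= 0, given G = C'C and c = C'd. Passive-set solves are
# on small G submatrices; singular solves fall back to a ridge-stabilised
# system.
nnls_gram <- function(G, c_vec, tol = NULL, max_iter = NULL) {
  n <- length(c_vec)
  max_iter <- max_iter %||% (3 * n)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(G)) * n)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  ls_sub <- function(idx) {
    Gs <- G[idx, idx, drop = FALSE]
    out <- tryCatch(solve(Gs, c_vec[idx]), error = function(e) NULL)
    if (is.null(out)) {
      out <- solve(Gs + diag(1e-10 * max(diag(Gs), 1), length(idx)), c_vec[idx])
    }
    out
  }
  for (outer in seq_len(max_iter)) {
    w <- c_vec - as.vector(G %*% x)
    w[passive] <- -Inf
    if (all(w <= tol)) break
    passive[which.max(w)] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- ls_sub(which(passive))
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio <- ratio[is.finite(ratio)]
      alpha <- if (length(ratio)) min(ratio) else 0
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
  }
  x
}

# Exact simplex-constrained least squares for many targets at once:
# for each row x of Targets, min ||x - w %*% Basis||^2 over the simplex.
# The optimum's support is one of the 2^k - 1 nonempty subsets; for each
# support the equality-constrained (sum-to-one) solution is linear in x, so
# it is computed for all rows simultaneously from the KKT inverse, and the
# feasible candidate with the smallest objective is exact. Used when k is
# small (the alternating A-step); falls back to per-row NNLS otherwise.
simplex_project <- function(Basis, Targets, enum_max_k = 10) {
  k <- nrow(Basis)
  if (k > enum_max_k) return(simplex_ls(Basis, Targets))
  n <- nrow(Targets)
  G <- Basis %*% t(Basis)              # k x k Gram
  Cmat <- Basis %*% t(Targets)         # k x n cross products
  best_obj <- rep(Inf, n)
  W <- matrix(1 / k, n, k)
  for (m in 1:(2^k - 1)) {
    S <- which(bitwAnd(m, bitwShiftL(1, 0:(k - 1))) > 0)
    s <- length(S)
    KKT <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, s), 0))
    Minv <- tryCatch(solve(KKT), error = function(e) NULL)
    if (is.null(Minv)) next
    # w_S = A c_S + b, candidate solution for every target column at once
    WS <- Minv[seq_len(s), seq_len(s), drop = FALSE] %*% Cmat[S, , drop = FALSE] +
      Minv[seq_len(s), s + 1]
    feasible <- colSums(WS < -1e-10) == 0
    if (!any(feasible)) next
    obj <- colSums(WS * (G[S, S, drop = FALSE] %*% WS)) - 2 * colSums(WS * Cmat[S, , drop = FALSE])
    upd <- feasible & obj < best_obj - 1e-15
    if (any(upd)) {
      best_obj[upd] <- obj[upd]
      W[upd, ] <- 0
      W[upd, S] <- t(pmax(WS[, upd, drop = FALSE], 0))
    }
  }
  W / rowSums(W)
}

# solve, for each row t of Targets, min ||t - w %*% Basis||^2 with w on the
# simplex, via NNLS on the sum-to-one-augmented system (a small ridge keeps
# passive-set solves full rank); `gram` = Basis %*% t(Basis) may be supplied
# to avoid recomputation across alternating iterations
simplex_ls <- function(Basis, Targets, big = 200, gram = NULL) {
  k <- nrow(Basis)
  ridge2 <- (1e-5 * max(abs(Basis), 1))^2
  if (is.null(gram)) gram <- Basis %*% t(Basis)
  G <- gram + big^2 + diag(ridge2, k)
  Ct <- Basis %*% t(Targets)           # k x n_targets cross products
  W <- t(vapply(seq_len(nrow(Targets)), function(i) {
    nnls_gram(G, Ct[, i] + big^2)
  }, numeric(k)))
  if (k == 1) W <- matrix(W, ncol = 1)
  s <- rowSums(W)
  s[s == 0] <- 1
  W / s
}

#' Scree of archetype fits over k
#'
#' Runs [archetypal_analysis()] for `k = 1:kmax` on the same seed set and
#' reports the best rss per k plus an advisory elbow (maximum second
#' difference of the rss curve).
#'
#' @inheritParams archetypal_analysis
#' @param kmax largest k (default 10)
#' @return list with `scree` (data.frame k, rss), `elbow`, and `solutions`
#' @export
select_k <- function(X, kmax = 10, nrep = 5, seed = 7L) {
  X <- as.matrix(X)
  if (kmax >= nrow(X)) stop_bad("kmax", "must be < n")
  sols <- lapply(seq_len(kmax), function(k)
    archetypal_analysis(X, k, nrep = nrep, seed = seed))
  rss <- vapply(sols, `[[`, numeric(1), "rss")
  rss <- cummin(rss)  # best-of-restarts is non-increasing in k by nesting
  elbow <- if (kmax >= 3) which.max(diff(diff(rss))) + 1L else NA_integer_
  list(scree = data.frame(k = seq_len(kmax), rss = rss),
       elbow = elbow, solutions = sols)
}

#' Assign observations to archetypes
#'
#' Recomputes simplex weights for (possibly new) rows of `X` against a
#' fitted solution's archetypes and returns the hard label (argmax weight,
#' ties to the lowest archetype index).
#'
#' @param X matrix of observations, d columns matching the fit
#' @param sol an `archetype_solution`
#' @return list with `weights` (n x k) and `labels` (integer vector)
#' @export
assign_archetype <- function(X, sol) {
  stopifnot(inherits(sol, "archetype_solution"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(sol$archetypes)) stop_bad("X", "column count must match the fitted archetypes")
  W <- simplex_project(sol$archetypes, X)
  labels <- apply(W, 1, which.max)  # which.max takes the first (lowest) index on ties
  list(weights = W, labels = as.integer(labels))
}
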