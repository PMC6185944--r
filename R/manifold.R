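#' Fit a task-specific PCA manifold
#'
#' Estimates the m-dimensional linear manifold of a neural population by PCA
#' of the smoothed firing rates: per-unit mean subtraction followed by
#' eigendecomposition of the unit covariance. Modes (principal components)
#' are ranked by variance; the sign of each mode is fixed so its
#' largest-magnitude element is positive.
#'
#' @param rates a `rate_matrix` (see [smooth_rates()]) or an n x T matrix.
#' @param m manifold dimensionality (default 12).
#' @return class `manifold`: `W` (n x m orthonormal mode basis), `mean`
#'   (length n), `eigenvalues` (full spectrum, nonincreasing), `m`, `task`.
#' @export
fit_pca <- function(rates, m = 12) {
  X <- if (inherits(rates, "rate_matrix")) rates$values else rates
  n <- nrow(X)
  if (m > n) stop("m exceeds the number of units", call. = FALSE)
  if (ncol(X) <= n)
    warning("fewer time bins than units; manifold estimate may be unstable")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  if (max(abs(C)) < .Machine$double.eps * n)
    stop("degenerate data: zero variance", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  W <- fix_mode_signs(e$vectors[, seq_len(m), drop = FALSE])
  structure(list(W = W, mean = mu, eigenvalues = pmax(e$values, 0), m = m,
                 task = if (inherits(rates, "rate_matrix")) rates$task else NULL),
            class = "manifold")
}

#' @export
print.manifold <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("<manifold> %d-D in %d-unit space; VAF %.1f%%\n",
              x$m, nrow(x$W),
              100 * sum(x$eigenvalues[seq_len(x$m)]) / tot))
  invisible(x)
}

#' Project population activity onto a manifold
#'
#' Latent activity `L = t(W) %*% (X - mean)`: the time course of each neural
#' mode's activation.
#'
#' @param rates a `rate_matrix` or n x T matrix.
#' @param manifold a [fit_pca()] manifold.
#' @return class `latent_activity`: `values` (m x T), `manifold`, `trials`
#'   (carried over when available), `bin_ms`.
#' @export
project <- function(rates, manifold) {
  X <- if (inherits(rates, "rate_matrix")) rates$values else rates
  if (nrow(X) != nrow(manifold$W))
    stop("unit count does not match the manifold", call. = FALSE)
  L <- crossprod(manifold$W, X - manifold$mean)
  structure(list(values = L, manifold = manifold,
                 trials = if (inherits(rates, "rate_matrix")) rates$trials,
                 bin_ms = if (inherits(rates, "rate_matrix")) rates$bin_ms
                          else NULL,
                 task = if (inherits(rates, "rate_matrix")) rates$task),
            class = "latent_activity")
}

#' Variance accounted for by an encoder/decoder pair
#'
#' Fractional variance accounted for in terms of the reconstruction error:
#' `VAF = (||X||^2 - ||X - D E X||^2) / ||X||^2` for a mean-subtracted data
#' matrix `X`, an h x n encoder `E` and an n x h decoder `D`. For an
#' orthonormal basis `W`, `E = t(W)`, `D = W` gives the projected-variance
#' fraction. For non-orthogonal manifold directions `M` within an orthonormal
#' basis `W`, use `E = t(M) %*% t(W)` and
#' `D = W %*% M %*% solve(crossprod(M))` (see [cca_vaf_pair()]).
#'
#' @param X n x T mean-subtracted data matrix (every row mean must be below
#'   1e-8 of the row s.d.).
#' @param E h x n encoding matrix.
#' @param D n x h decoding matrix.
#' @return scalar VAF.
#' @export
vaf <- function(X, E, D) {
  rm_ <- rowMeans(X)
  rs <- apply(X, 1, stats::sd)
  if (any(abs(rm_) > 1e-8 * pmax(rs, .Machine$double.eps)))
    stop("contract violation: X must be mean-subtracted per row",
         call. = FALSE)
  tot <- sum(X^2)
  rec <- D %*% (E %*% X)
  (tot - sum((X - rec)^2)) / tot
}

# Center a rate matrix per unit.
centered_rates <- function(rates) {
  X <- if (inherits(rates, "rate_matrix")) rates$values else rates
  X - rowMeans(X)
}

#' Across-task to within-task VAF ratio
#'
#' Projects the data of task A onto the manifold of task B and compares the
#' variance accounted for to that of task A's own manifold. Ratios near one
#' indicate similarly oriented manifolds.
#'
#' @param rates_a task A data (`rate_matrix` or matrix).
#' @param manifold_a,manifold_b manifolds of tasks A and B.
#' @return scalar ratio `VAF(A onto B) / VAF(A onto A)`.
#' @export
across_task_vaf_ratio <- function(rates_a, manifold_a, manifold_b) {
  Xc <- centered_rates(rates_a)
  within <- vaf(Xc, t(manifold_a$W), manifold_a$W)
  if (within <= 0)
    stop("within-task VAF is zero; ratio undefined", call. = FALSE)
  vaf(Xc, t(manifold_b$W), manifold_b$W) / within
}

#' Chance-level across-task VAF from random manifolds
#'
#' Projects the data onto `n_draws` Haar-uniform random m-dimensional
#' manifolds and returns the chance ceiling of the across-task VAF ratio:
#' the 99.9th percentile of the random-manifold VAF distribution divided by
#' the within-task VAF.
#'
#' @param rates task data (`rate_matrix` or matrix).
#' @param m manifold dimensionality.
#' @param n_draws number of random manifolds (default 10000; >= 100).
#' @param probs percentile of the chance distribution (default 0.999).
#' @return list with `ratio_threshold`, `vaf_threshold`, `within_vaf`, and
#'   the vector of random-manifold `vafs`.
#' @export
random_manifold_control <- function(rates, m, n_draws = 10000,
                                    probs = 0.999) {
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  Xc <- centered_rates(rates)
  n <- nrow(Xc)
  if (m > n) stop("m exceeds the number of units", call. = FALSE)
  tot <- sum(Xc^2)
  vafs <- vapply(seq_len(n_draws), function(i) {
    W <- random_orthonormal(n, m)
    sum(crossprod(W, Xc)^2) / tot
  }, numeric(1))
  mani <- fit_pca(if (inherits(rates, "rate_matrix")) rates else Xc, m)
  within <- sum(mani$eigenvalues[seq_len(m)]) / sum(mani$eigenvalues)
  thr <- stats::quantile(vafs, probs, names = FALSE)
  list(ratio_threshold = thr / within, vaf_threshold = thr,
       within_vaf = within, vafs = vafs)
}
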