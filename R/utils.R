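# Internal numerical helpers shared across modules.

softplus <- function(x) {
  # stable: log(1 + exp(x)) = max(x, 0) + log1p(exp(-|x|))
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out[x == -Inf] <- 0
  out
}

inv_softplus <- function(y) {
  stopifnot(all(y >= 0))
  out <- ifelse(y > 30, y, log(expm1(pmin(y, 30))))
  out[y == 0] <- -Inf
  out
}

# Gaussian kernel truncated at +/- 4 s.d., renormalized to unit mass.
gauss_kernel <- function(sd_bins) {
  stopifnot(sd_bins > 0)
  half <- max(1L, ceiling(4 * sd_bins))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sd_bins^2))
  k / sum(k)
}

# Convolve each row of `mat` with `kernel` (odd length), zero-padded edges.
smooth_rows <- function(mat, kernel) {
  half <- (length(kernel) - 1L) / 2L
  Tn <- ncol(mat)
  padded <- cbind(matrix(0, nrow(mat), half), mat, matrix(0, nrow(mat), half))
  out <- matrix(0, nrow(mat), Tn)
  for (j in seq_len(Tn)) {
    out[, j] <- padded[, j:(j + 2L * half), drop = FALSE] %*% kernel
  }
  out
}

# Evaluate a function under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_orthonormal <- function(W, tol = 1e-8) {
  d <- crossprod(W) - diag(ncol(W))
  max(abs(d)) < tol
}

# Haar-uniform random n x m orthonormal basis: QR of a standard-normal matrix
# with the R-diagonal sign correction.
random_orthonormal <- function(n, m) {
  stopifnot(m <= n)
  qd <- qr(matrix(rnorm(n * m), n, m))
  Q <- qr.Q(qd)
  s <- sign(diag(qr.R(qd)))
  s[s == 0] <- 1
  sweep(Q, 2, s, `*`)
}

# Fix eigenvector/mode signs: largest-magnitude element positive.
fix_mode_signs <- function(W) {
  s <- apply(W, 2, function(w) {
    v <- w[which.max(abs(w))]
    if (v < 0) -1 else 1
  })
  sweep(W, 2, s, `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
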