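# Tensor-maximum-entropy surrogates.
#
# The null model draws random tensors from the maximum-entropy Gaussian whose
# expected marginal covariances over the preserved tensor dimensions (time,
# condition) match those of the data, while the neuron marginal is
# constrained only to an isotropic target (total variance / n) so that
# covariance across neurons is destroyed. The maximum-entropy covariance has
# Kronecker-structured eigenvectors (those of the marginal covariances) and
# eigenvalues 1 / (lT_i + lN_j + lC_k), with the Lagrange multipliers l found
# by minimizing the convex dual.

# Fit the TME model to an n x C x tau tensor (neuron, condition, time).
tme_fit <- function(x, preserve = c("time", "condition"),
                    eig_floor = 1e-9, maxit = 2000) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]; C <- dim(x)[2]; tau <- dim(x)[3]
  mu <- apply(x, 1, mean)
  xc <- x - array(mu, dim(x))  # per-neuron centering
  tot <- sum(xc^2)

  marg_cov <- function(axis) {
    perm <- switch(axis, time = c(3, 1, 2), condition = c(2, 1, 3),
                   neuron = c(1, 2, 3))
    M <- apply(xc, perm[1], function(s) s)  # unfold: (other dims) x axis
    crossprod(M)
  }
  S_T <- if ("time" %in% preserve) marg_cov("time") else
    diag(tot / tau, tau)
  S_C <- if ("condition" %in% preserve) marg_cov("condition") else
    diag(tot / C, C)
  # neuron marginal: isotropic (variance scale only)
  d_N <- rep(tot / n, n)

  floor_eig <- function(d) {
    fl <- eig_floor * max(d)
    floored <- d < fl
    list(d = pmax(d, fl), floored = any(floored))
  }
  eT <- eigen(S_T, symmetric = TRUE)
  eC <- eigen(S_C, symmetric = TRUE)
  fT <- floor_eig(eT$values); fC <- floor_eig(eC$values)
  d_T <- fT$d; d_C <- fC$d

  # consistency: all marginal traces must equal the total sum of squares
  d_T <- d_T / sum(d_T) * tot
  d_C <- d_C / sum(d_C) * tot

  # convex dual: minimize -sum log(s) + <l, d> with s_ijk = lT_i+lN_j+lC_k
  idx_T <- seq_len(tau); idx_N <- tau + seq_len(n)
  idx_C <- tau + n + seq_len(C)
  obj <- function(l) {
    S <- outer(outer(l[idx_T], l[idx_N], `+`), l[idx_C], `+`)
    if (any(S <= 0)) return(1e12)
    -sum(log(S)) + sum(l[idx_T] * d_T) + sum(l[idx_N] * d_N) +
      sum(l[idx_C] * d_C)
  }
  grad <- function(l) {
    S <- outer(outer(l[idx_T], l[idx_N], `+`), l[idx_C], `+`)
    if (any(S <= 0)) S[S <= 0] <- 1e-12
    R <- 1 / S
    c(d_T - apply(R, 1, sum), d_N - apply(R, 2, sum),
      d_C - apply(R, 3, sum))
  }
  l0 <- c(n * C / (3 * d_T), tau * C / (3 * d_N), tau * n / (3 * d_C))
  fit <- stats::optim(l0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  l <- fit$par
  S <- outer(outer(l[idx_T], l[idx_N], `+`), l[idx_C], `+`)
  structure(list(Q_T = eT$vectors, Q_C = eC$vectors,
                 sqrt_s = sqrt(1 / S),  # dims: tau x n x C
                 n = n, C = C, tau = tau, mu = mu, total_ss = tot,
                 d_T = d_T, d_C = d_C,
                 floored = fT$floored || fC$floored,
                 convergence = fit$convergence,
                 grad_norm = max(abs(grad(l)) / tot)),
            class = "tme_model")
}

# One surrogate draw: n x C x tau tensor with the fitted marginal structure.
tme_sample <- function(model) {
  z <- array(stats::rnorm(model$tau * model$n * model$C),
             c(model$tau, model$n, model$C)) * model$sqrt_s
  # rotate the time axis
  y <- array(model$Q_T %*% matrix(z, model$tau), dim(z))
  # rotate the condition axis
  y <- aperm(y, c(3, 1, 2))                       # C x tau x n
  y <- array(model$Q_C %*% matrix(y, model$C), dim(y))
  aperm(y, c(3, 1, 2))                            # n x C x tau
}

# Unfold an n x C x tau tensor to the n x (C*tau) concatenated matrix.
unfold_nct <- function(x) matrix(x, dim(x)[1])

# Top-m PCA basis of a (centered) n x T matrix.
pca_basis <- function(X, m) {
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  fix_mode_signs(e$vectors[, seq_len(m), drop = FALSE])
}

#' Surrogate ensemble of principal angles under a covariance-preserving null
#'
#' Generates pairs of surrogate datasets that preserve the trial-averaged
#' data's covariance over time and across targets but destroy covariance
#' across neurons, processes each surrogate through the same pipeline as the
#' real data (concatenate conditions, PCA, principal angles between the pair
#' of surrogate manifolds), and returns the per-rank angle distributions used
#' to judge whether observed angles are significantly small.
#'
#' @param tensor a [trial_average()] tensor containing (at least) the two
#'   tasks being compared, or a list of two n x gamma x tau arrays.
#' @param n_surrogates number of surrogate pairs (default 10000; >= 100).
#' @param m manifold dimensionality (scalar, or vector — e.g. `c(8, 12, 15)`
#'   for a dimensionality sweep; angle matrices are stored per m).
#' @param tasks indices of the two tasks to compare (default first two).
#' @param preserve marginals to preserve: subset of
#'   `c("time", "condition")`.
#' @param method `"tme"` (maximum-entropy Gaussian, default) or `"shuffle"`
#'   (independent permutation of unit identities per surrogate; fast
#'   fallback preserving each unit's temporal profile).
#' @return class `surrogate_ensemble` with per-m angle matrices
#'   (`n_surrogates` x m), stored surrogate manifold bases up to `max(m)`,
#'   fitted models, and diagnostics.
#' @export
tme_surrogates <- function(tensor, n_surrogates = 10000, m = 12,
                           tasks = c(1, 2),
                           preserve = c("time", "condition"),
                           method = c("tme", "shuffle")) {
  method <- match.arg(method)
  if (n_surrogates < 100) stop("n_surrogates must be >= 100", call. = FALSE)
  if (inherits(tensor, "trial_tensor")) {
    stopifnot(length(tensor$tasks) >= 2)
    arr_a <- tensor$values[, tasks[1], , , drop = FALSE]
    arr_b <- tensor$values[, tasks[2], , , drop = FALSE]
    dim(arr_a) <- dim(tensor$values)[c(1, 3, 4)]
    dim(arr_b) <- dim(tensor$values)[c(1, 3, 4)]
  } else {
    arr_a <- tensor[[1]]; arr_b <- tensor[[2]]
  }
  if (!all(is.finite(arr_a)) || !all(is.finite(arr_b)))
    stop("tensor must be finite", call. = FALSE)
  m_max <- max(m)
  n <- dim(arr_a)[1]
  if (m_max > n) stop("m exceeds the number of units", call. = FALSE)

  draw_fun <- if (method == "tme") {
    mod_a <- tme_fit(arr_a, preserve)
    mod_b <- tme_fit(arr_b, preserve)
    function() list(tme_sample(mod_a), tme_sample(mod_b))
  } else {
    mod_a <- mod_b <- NULL
    Xa <- unfold_nct(arr_a); Xb <- unfold_nct(arr_b)
    function() list(Xa[sample.int(n), , drop = FALSE],
                    Xb[sample.int(n), , drop = FALSE])
  }

  bases_a <- vector("list", n_surrogates)
  bases_b <- vector("list", n_surrogates)
  # accumulate time-marginal covariance of side-A draws for diagnostics
  tau <- dim(arr_a)[3]
  time_cov_acc <- matrix(0, tau, tau)
  cond_cov_acc <- matrix(0, dim(arr_a)[2], dim(arr_a)[2])
  for (i in seq_len(n_surrogates)) {
    s <- draw_fun()
    sa <- if (is.matrix(s[[1]])) s[[1]] else unfold_nct(s[[1]])
    sb <- if (is.matrix(s[[2]])) s[[2]] else unfold_nct(s[[2]])
    if (method == "tme") {
      a3 <- s[[1]]
      ac <- a3 - array(apply(a3, 1, mean), dim(a3))
      Mt <- matrix(aperm(ac, c(3, 1, 2)), tau)
      time_cov_acc <- time_cov_acc + tcrossprod(Mt)
      Mc <- matrix(aperm(ac, c(2, 1, 3)), dim(a3)[2])
      cond_cov_acc <- cond_cov_acc + tcrossprod(Mc)
    }
    bases_a[[i]] <- pca_basis(sa, m_max)
    bases_b[[i]] <- pca_basis(sb, m_max)
  }
  ens <- structure(list(bases_a = bases_a, bases_b = bases_b,
                        m_max = m_max, angles = list(),
                        n_surrogates = n_surrogates, method = method,
                        models = list(a = mod_a, b = mod_b),
                        mean_time_cov = time_cov_acc / n_surrogates,
                        mean_cond_cov = cond_cov_acc / n_surrogates,
                        target_time_cov = if (method == "tme")
                          with(mod_a, Q_T %*% (d_T * t(Q_T))),
                        target_cond_cov = if (method == "tme")
                          with(mod_a, Q_C %*% (d_C * t(Q_C)))),
                   class = "surrogate_ensemble")
  for (mm in m)
    ens$angles[[as.character(mm)]] <- surrogate_angles(ens, mm)
  ens
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d pairs, method %s, m up to %d\n",
              x$n_surrogates, x$method, x$m_max))
  invisible(x)
}
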