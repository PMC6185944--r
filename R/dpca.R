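#' Factorial marginalization of a trial-averaged tensor
#'
#' Decomposes the mean-subtracted trial-averaged tensor into additive
#' components attributable to each behavioral parameter: time (condition
#' mean), task (task means minus the time term), target (target means minus
#' the time term), and the task/target interaction (remainder). The four
#' components sum to the mean-subtracted tensor exactly and are pairwise
#' uncorrelated under a balanced design.
#'
#' @param tensor a [trial_average()] tensor (balanced: all task x target
#'   conditions present with equal duration).
#' @return class `dpca_marginalization`: list of arrays (`time`, `task`,
#'   `target`, `task_target`, each n x alpha x gamma x tau), the per-neuron
#'   `grand_mean`, and the centered tensor `centered`.
#' @export
marginalize <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  X <- tensor$values
  dn <- dim(X)
  grand <- apply(X, 1, mean)
  Xc <- X - array(grand, dn)
  tm <- apply(Xc, c(1, 4), mean)                  # n x tau
  time_arr <- aperm(array(tm, c(dn[1], dn[4], dn[2], dn[3])),
                    c(1, 3, 4, 2))
  am <- apply(Xc, c(1, 2, 4), mean)               # n x alpha x tau
  task_arr <- aperm(array(am, c(dn[1], dn[2], dn[4], dn[3])),
                    c(1, 2, 4, 3)) - time_arr
  gm <- apply(Xc, c(1, 3, 4), mean)               # n x gamma x tau
  target_arr <- aperm(array(gm, c(dn[1], dn[3], dn[4], dn[2])),
                      c(1, 4, 2, 3)) - time_arr
  tt_arr <- Xc - time_arr - task_arr - target_arr
  structure(list(time = time_arr, task = task_arr, target = target_arr,
                 task_target = tt_arr, grand_mean = grand, centered = Xc,
                 dims = dn),
            class = "dpca_marginalization")
}

# Unfold an n x alpha x gamma x tau array to n x (alpha*gamma*tau).
unfold_tensor <- function(x) matrix(x, dim(x)[1])

#' Demixed PCA of a trial-averaged tensor
#'
#' For each marginalization, solves the least-squares reconstruction
#' `A = X_phi %*% t(X) %*% solve(X %*% t(X))` (X the unfolded mean-subtracted
#' tensor) and reduces it to low rank by SVD of `A %*% X`. Candidate modes
#' from all marginalizations are pooled, ranked by variance accounted for,
#' and the top m kept. Decoders (reconstruction directions) are orthonormal
#' within a marginalization; encoders are the matching rows of the
#' rank-reduced regression map and need not be orthogonal to each other.
#'
#' @param tensor a [trial_average()] tensor.
#' @param m number of modes to keep (default 12).
#' @param ridge optional ridge penalty (fraction of `mean(diag(XX^T))`) used
#'   only when `X %*% t(X)` is singular; 0 for the analytic solution.
#' @return class `dpca`: `encoder` (m x n), `decoder` (n x m), `labels`
#'   (marginalization of each mode), `mode_vaf`, `total_vaf`, `grand_mean`,
#'   `marginalization`, and bookkeeping fields.
#' @export
fit_dpca <- function(tensor, m = 12, ridge = 0) {
  marg <- marginalize(tensor)
  n <- marg$dims[1]
  if (m > n) stop("m exceeds the number of units", call. = FALSE)
  X <- unfold_tensor(marg$centered)
  XXt <- tcrossprod(X)
  if (ridge > 0) XXt <- XXt + diag(ridge * mean(diag(XXt)), n)
  XXt_inv <- tryCatch(solve(XXt), error = function(e) {
    message("singular covariance; applying ridge fallback")
    solve(XXt + diag(1e-8 * mean(diag(XXt)), n))
  })
  tot <- sum(X^2)
  labels <- c("time", "task", "target", "task_target")
  cand <- list()
  for (lab in labels) {
    Xphi <- unfold_tensor(marg[[lab]])
    A <- Xphi %*% t(X) %*% XXt_inv
    s <- svd(A %*% X, nu = min(m, n), nv = 0)
    r <- min(m, sum(s$d > max(s$d[1], 0) * 1e-12))
    for (p in seq_len(r)) {
      u <- s$u[, p]
      if (u[which.max(abs(u))] < 0) u <- -u
      e_row <- crossprod(u, A)               # 1 x n encoder
      proj <- e_row %*% X                    # 1 x T latent
      rec_ss <- sum(proj^2)                  # ||u proj||^2, u unit norm
      vaf_p <- (2 * sum(proj * (crossprod(u, X))) - rec_ss) / tot
      cand[[length(cand) + 1L]] <- list(label = lab, u = u,
                                        e = as.numeric(e_row),
                                        vaf = vaf_p)
    }
  }
  ord <- order(vapply(cand, `[[`, 0, "vaf"), decreasing = TRUE)
  keep <- cand[ord[seq_len(min(m, length(cand)))]]
  decoder <- vapply(keep, `[[`, numeric(n), "u")
  encoder <- t(vapply(keep, `[[`, numeric(n), "e"))
  mode_vaf <- vapply(keep, `[[`, 0, "vaf")
  total_vaf <- (tot - sum((X - decoder %*% (encoder %*% X))^2)) / tot
  structure(list(encoder = encoder, decoder = decoder,
                 labels = vapply(keep, `[[`, "", "label"),
                 mode_vaf = mode_vaf, total_vaf = total_vaf,
                 grand_mean = marg$grand_mean, marginalization = marg,
                 m = length(keep), dims = marg$dims,
                 tasks = tensor$tasks, targets = tensor$targets),
            class = "dpca")
}

#' @export
print.dpca <- function(x, ...) {
  cat(sprintf("<dpca> %d modes, total VAF %.1f%%\n", x$m,
              100 * x$total_vaf))
  tab <- label_modes(x)$parameter_vaf
  for (lab in names(tab))
    cat(sprintf("  %-12s %5.1f%%\n", lab, 100 * tab[lab]))
  invisible(x)
}

#' Cumulative VAF curve for an encoder/decoder pair on a tensor
#'
#' Reconstruction-error VAF of the mean-subtracted unfolded tensor under the
#' leading h modes, honoring non-orthogonal decoders:
#' `VAF_h = (||X||^2 - ||X - D_h E_h X||^2) / ||X||^2`.
#'
#' @param tensor a [trial_average()] tensor (or an already-centered n x T
#'   matrix).
#' @param E m x n encoder.
#' @param D n x m decoder.
#' @return numeric vector of cumulative VAF for h = 0..m (first element 0).
#' @export
dpca_vaf <- function(tensor, E, D) {
  X <- if (inherits(tensor, "trial_tensor")) {
    Xc <- tensor$values - array(apply(tensor$values, 1, mean),
                                dim(tensor$values))
    unfold_tensor(Xc)
  } else tensor
  if (ncol(E) != nrow(X) || nrow(D) != nrow(X))
    stop("encoder/decoder shape mismatch", call. = FALSE)
  tot <- sum(X^2)
  c(0, vapply(seq_len(nrow(E)), function(h) {
    Eh <- E[seq_len(h), , drop = FALSE]
    Dh <- D[, seq_len(h), drop = FALSE]
    (tot - sum((X - Dh %*% (Eh %*% X))^2)) / tot
  }, numeric(1)))
}

#' Mode labels and per-parameter VAF totals of a dPCA fit
#'
#' @param result a [fit_dpca()] result.
#' @return list with `labels` (per kept mode) and `parameter_vaf` (named
#'   totals of mode VAF per behavioral parameter).
#' @export
label_modes <- function(result) {
  stopifnot(inherits(result, "dpca"))
  labs <- c("time", "task", "target", "task_target")
  totals <- vapply(labs, function(l) sum(result$mode_vaf[result$labels == l]),
                   numeric(1))
  list(labels = result$labels, parameter_vaf = totals)
}

# Single-trial latent activity on dPCA axes: encoder rows applied to the
# centered single-trial rates (centered with the tensor's grand mean).
dpca_latents <- function(result, rates) {
  X <- if (inherits(rates, "rate_matrix")) rates$values else rates
  result$encoder %*% (X - result$grand_mean)
}
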