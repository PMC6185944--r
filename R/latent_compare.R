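# Window extraction shared by match_and_concat and the within-task ceiling:
# column indices of the first `w` bins of the chosen trials, concatenated by
# ascending target, then trial order.
matched_window_cols <- function(trials, chosen, w) {
  unlist(lapply(chosen, function(i) trials$go[i]:(trials$go[i] + w - 1L)))
}

# Pick per-target trial indices (first k successful trials each), ordered by
# ascending common target label.
pick_matched_trials <- function(trials, k, targets) {
  unlist(lapply(targets, function(g) {
    idx <- which(trials$target == g & trials$success)
    idx[seq_len(k)]
  }))
}

#' Target-matched, trial-equalized latent activity for a task pair
#'
#' Prepares the two latent activity matrices compared by CCA: equalizes the
#' number of trials across all tasks and targets (k = minimum successful
#' trial count over all conditions of the pair), takes a fixed window from
#' each trial starting at target onset (default 700 ms), orders trials by a
#' common target sequence, projects each task's windows onto its own PCA
#' manifold, and concatenates.
#'
#' @param session a `neural_session` (see [generate_session()]).
#' @param task_a,task_b task labels.
#' @param window_ms window length in ms from target onset (clamped, with a
#'   warning, to the shortest trial).
#' @param m manifold dimensionality.
#' @param kernel_sd smoothing kernel s.d. in ms.
#' @param target_map optional function mapping each task's target labels to
#'   common labels (e.g. [horizontal_target_map()] for a 2-D task compared
#'   to 1-D tasks).
#' @return list with `L_a`, `L_b` (m x T latent matrices), the fitted
#'   `manifold_a`/`manifold_b`, `k`, and window length in bins.
#' @export
match_and_concat <- function(session, task_a, task_b, window_ms = 700,
                             m = 12, kernel_sd = 50, target_map = NULL) {
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms, kernel_sd = kernel_sd)
  match_core(rates, task_a, task_b, window_ms = window_ms, m = m,
             target_map = target_map, bin_ms = session$bin_ms)
}

# Core of match_and_concat, operating on any full-session rate-matrix-like
# object (also used for EMG latent comparisons).
match_core <- function(rates, task_a, task_b, window_ms = 700, m = 12,
                       target_map = NULL, bin_ms = 20) {
  ra <- task_rates(rates, task_a)
  rb <- task_rates(rates, task_b)
  if (!is.null(target_map)) {
    ra$trials$target <- target_map(ra$trials$target)
    rb$trials$target <- target_map(rb$trials$target)
  }
  targets <- sort(intersect(unique(ra$trials$target),
                            unique(rb$trials$target)))
  extra <- setdiff(union(unique(ra$trials$target), unique(rb$trials$target)),
                   targets)
  if (length(extra))
    stop("unmatched target label(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  counts <- c(vapply(targets, function(g)
                sum(ra$trials$target == g & ra$trials$success), 0L),
              vapply(targets, function(g)
                sum(rb$trials$target == g & rb$trials$success), 0L))
  k <- min(counts)
  if (k == 0) stop("matching error: a condition has no successful trials",
                   call. = FALSE)
  w <- round(window_ms / bin_ms)
  shortest <- min(c(ra$trials$end - ra$trials$go,
                    rb$trials$end - rb$trials$go)) + 1L
  if (w > shortest) {
    warning("window clamped from ", w, " to ", shortest, " bins")
    w <- shortest
  }
  mani_a <- fit_pca(ra, m)
  mani_b <- fit_pca(rb, m)
  cols_a <- matched_window_cols(ra$trials,
                                pick_matched_trials(ra$trials, k, targets), w)
  cols_b <- matched_window_cols(rb$trials,
                                pick_matched_trials(rb$trials, k, targets), w)
  L_a <- crossprod(mani_a$W, ra$values[, cols_a, drop = FALSE] - mani_a$mean)
  L_b <- crossprod(mani_b$W, rb$values[, cols_b, drop = FALSE] - mani_b$mean)
  list(L_a = L_a, L_b = L_b, manifold_a = mani_a, manifold_b = mani_b,
       k = k, window_bins = w, targets = targets)
}

#' Map 2-D center-out target angles to 1-D labels
#'
#' Groups targets of a 2-D center-out task by the sign of their projection
#' onto the horizontal axis, so they can be matched to the two directions of
#' a 1-D task.
#'
#' @param angles_deg target angles in degrees.
#' @return integer labels: 1 for positive horizontal projection, 2 for
#'   negative; targets on the vertical meridian get NA.
#' @export
horizontal_target_map <- function(angles_deg) {
  p <- cos(angles_deg * pi / 180)
  out <- ifelse(abs(p) < 1e-9, NA_integer_, ifelse(p > 0, 1L, 2L))
  out
}

#' Canonical correlation analysis of two latent activity matrices
#'
#' Finds, rank by rank, paired directions within two m-dimensional latent
#' spaces whose projected activities are maximally correlated: QR
#' decomposition of the transposed (row-centered) latent matrices, SVD of
#' the inner-product of the orthonormal factors, and back-transform of the
#' singular vectors through the triangular factors.
#'
#' @param L_a,L_b m x T latent activity matrices (or `latent_activity`
#'   objects) with equal T > m.
#' @return class `cca_result`: `correlations` (length m, nonincreasing, in
#'   [0, 1]), the transform matrices `M_a`, `M_b` (m x m), and the aligned
#'   canonical variates `aligned_a`, `aligned_b` (m x T, unit norm).
#' @export
cca <- function(L_a, L_b) {
  if (inherits(L_a, "latent_activity")) L_a <- L_a$values
  if (inherits(L_b, "latent_activity")) L_b <- L_b$values
  stopifnot(ncol(L_a) == ncol(L_b))
  m_a <- nrow(L_a); m_b <- nrow(L_b)
  if (ncol(L_a) <= max(m_a, m_b))
    stop("T must exceed the latent dimensionality", call. = FALSE)
  Ac <- L_a - rowMeans(L_a)
  Bc <- L_b - rowMeans(L_b)
  qa <- qr(t(Ac)); qb <- qr(t(Bc))
  Ra <- qr.R(qa); Rb <- qr.R(qb)
  tol <- 1e-10
  if (any(abs(diag(Ra)) < tol * max(abs(diag(Ra)))))
    stop("rank error: latent matrix A is rank deficient", call. = FALSE)
  if (any(abs(diag(Rb)) < tol * max(abs(diag(Rb)))))
    stop("rank error: latent matrix B is rank deficient", call. = FALSE)
  Qa <- qr.Q(qa); Qb <- qr.Q(qb)
  s <- svd(crossprod(Qa, Qb))
  cc <- pmin(pmax(s$d, 0), 1)
  M_a <- backsolve(Ra, s$u)
  M_b <- backsolve(Rb, s$v)
  structure(list(correlations = cc, M_a = M_a, M_b = M_b,
                 aligned_a = t(Qa %*% s$u), aligned_b = t(Qb %*% s$v)),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result> canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Within-task ceiling for across-task canonical correlations
#'
#' Estimates the best correlation attainable given trial-to-trial
#' variability: trials of one task are split into two random target-matched
#' halves, the full latent pipeline (windowing, per-half PCA, projection) is
#' run on each half, and the halves are compared with CCA. Repeated
#' `n_reps` times; the ceiling is the 99.9th percentile per rank.
#'
#' @param session a `neural_session`.
#' @param task task label.
#' @param n_reps number of random splits (default 100).
#' @param window_ms,m,kernel_sd as in [match_and_concat()].
#' @param probs percentile for the ceiling (default 0.999).
#' @return list with `ceiling` (length m) and the `draws` matrix
#'   (n_reps x m).
#' @export
within_task_ceiling <- function(session, task, n_reps = 100,
                                window_ms = 700, m = 12, kernel_sd = 50,
                                probs = 0.999) {
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms, kernel_sd = kernel_sd)
  rt <- task_rates(rates, task)
  targets <- sort(unique(rt$trials$target))
  per_target <- lapply(targets, function(g)
    which(rt$trials$target == g & rt$trials$success))
  if (any(vapply(per_target, length, 0L) < 2))
    stop("need >= 2 successful trials per condition", call. = FALSE)
  w <- round(window_ms / session$bin_ms)
  shortest <- min(rt$trials$end - rt$trials$go) + 1L
  if (w > shortest) {
    warning("window clamped from ", w, " to ", shortest, " bins")
    w <- shortest
  }
  half_latents <- function(chosen) {
    cols <- matched_window_cols(rt$trials, chosen, w)
    X <- rt$values[, cols, drop = FALSE]
    mani <- fit_pca(X, m)
    crossprod(mani$W, X - mani$mean)
  }
  draws <- t(vapply(seq_len(n_reps), function(r) {
    h1 <- integer(0); h2 <- integer(0)
    for (idx in per_target) {
      k2 <- length(idx) %/% 2L          # odd counts: one trial dropped
      sh <- sample(idx)
      h1 <- c(h1, sort(sh[seq_len(k2)]))
      h2 <- c(h2, sort(sh[k2 + seq_len(k2)]))
    }
    cca(half_latents(h1), half_latents(h2))$correlations
  }, numeric(m)))
  list(ceiling = apply(draws, 2, stats::quantile, probs = probs,
                       names = FALSE),
       draws = draws)
}

#' Bootstrap null for across-task canonical correlations
#'
#' Destroys the temporal correspondence between the two latent sets while
#' matching their spectral content: the time columns of one side are
#' permuted jointly across modes and re-smoothed with a Gaussian kernel
#' (s.d. 50 ms), then compared with CCA. The per-rank threshold is the
#' 99.9th percentile over draws (significance P < 0.001).
#'
#' @param L_a,L_b m x T latent matrices.
#' @param n_boot number of bootstrap draws (default 5000).
#' @param kernel_sd smoothing kernel s.d. in ms.
#' @param bin_ms bin width in ms.
#' @param probs percentile of the null distribution (default 0.999).
#' @return list with `threshold` (length m) and `draws` (n_boot x m).
#' @export
bootstrap_null <- function(L_a, L_b, n_boot = 5000, kernel_sd = 50,
                           bin_ms = 20, probs = 0.999) {
  if (inherits(L_a, "latent_activity")) L_a <- L_a$values
  if (inherits(L_b, "latent_activity")) L_b <- L_b$values
  if (n_boot * (1 - probs) < 1)
    stop("resolution error: n_boot x (1 - probs) < 1", call. = FALSE)
  kernel <- gauss_kernel(kernel_sd / bin_ms)
  if (length(kernel) >= ncol(L_a) / 4)
    stop("T too short relative to the smoothing kernel", call. = FALSE)
  m <- nrow(L_a)
  draws <- t(vapply(seq_len(n_boot), function(b) {
    perm <- L_a[, sample.int(ncol(L_a)), drop = FALSE]
    cca(smooth_rows(perm, kernel), L_b)$correlations
  }, numeric(m)))
  list(threshold = apply(draws, 2, stats::quantile, probs = probs,
                         names = FALSE),
       draws = draws)
}

#' Cumulative VAF of CCA-aligned manifold directions
#'
#' Variance accounted for when the data are encoded through the leading h
#' CCA directions (`E_h = t(M_h) %*% t(W)`) and optimally decoded. Because
#' `M` is not orthogonal, the decoder carries the correction
#' `D_h = W %*% M_h %*% solve(t(M_h) %*% M_h)`.
#'
#' @param rates task data (`rate_matrix` or matrix; centered internally).
#' @param manifold the task's [fit_pca()] manifold.
#' @param M the task's m x m CCA transform (`M_a` or `M_b` of [cca()]).
#' @return numeric vector: cumulative VAF for h = 1..m.
#' @export
cca_vaf <- function(rates, manifold, M) {
  Xc <- centered_rates(rates)
  W <- manifold$W
  vapply(seq_len(ncol(M)), function(h) {
    Mh <- M[, seq_len(h), drop = FALSE]
    E <- crossprod(Mh, t(W))
    D <- W %*% Mh %*% solve(crossprod(Mh))
    vaf(Xc, E, D)
  }, numeric(1))
}
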