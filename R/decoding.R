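# Lagged design matrix: column block per input, lags 0..M-1 into the past,
# zero-padded before the start of the record.
lagged_design <- function(latents, M) {
  K <- nrow(latents); Tn <- ncol(latents)
  Z <- matrix(0, Tn, K * M)
  for (k in seq_len(K)) for (lag in 0:(M - 1)) {
    col <- (k - 1) * M + lag + 1L
    if (lag < Tn)
      Z[(lag + 1):Tn, col] <- latents[k, 1:(Tn - lag)]
  }
  Z
}

#' Fit a Wiener cascade EMG decoder
#'
#' Multiple-input single-output linear filter (K inputs x M lags into the
#' past, coefficients from the lagged auto-/cross-correlation normal
#' equations, i.e. least squares) followed by a static second-order
#' polynomial nonlinearity `z = a + b*y + c*y^2` fitted by least squares.
#'
#' @param latents K x T input latent activity.
#' @param emg length-T target EMG channel.
#' @param M_lags number of lags (default 10 bins = 200 ms at 20 ms bins).
#' @param ridge ridge penalty applied only if the normal equations are
#'   singular.
#' @return class `wiener_cascade` with `h` (K x M filter coefficients),
#'   `intercept`, polynomial `poly = c(a, b, c)`, `K`, `M`.
#' @export
fit_wiener_cascade <- function(latents, emg, M_lags = 10, ridge = 1e-8) {
  if (is.vector(latents)) latents <- matrix(latents, 1)
  K <- nrow(latents); Tn <- ncol(latents)
  stopifnot(length(emg) == Tn, M_lags >= 1)
  if (Tn <= K * M_lags + 3)
    stop("T must exceed K * M_lags + 3", call. = FALSE)
  if (!all(is.finite(latents)) || !all(is.finite(emg)))
    stop("inputs must be finite", call. = FALSE)
  Z <- cbind(1, lagged_design(latents, M_lags))
  G <- crossprod(Z)
  coef <- tryCatch(solve(G, crossprod(Z, emg)), error = function(e) {
    message("singular normal equations; applying ridge")
    solve(G + diag(ridge * mean(diag(G)), ncol(G)), crossprod(Z, emg))
  })
  y <- as.numeric(Z %*% coef)
  P <- cbind(1, y, y^2)
  PtP <- crossprod(P)
  poly <- tryCatch(as.numeric(solve(PtP, crossprod(P, emg))),
                   error = function(e) c(mean(emg), 0, 0))
  structure(list(h = matrix(coef[-1], K, M_lags, byrow = TRUE),
                 intercept = coef[1], poly = as.numeric(poly),
                 K = K, M = M_lags),
            class = "wiener_cascade")
}

#' Predict EMG from latent activity with a fitted Wiener cascade
#'
#' @param object a [fit_wiener_cascade()] decoder.
#' @param latents K x T latent activity.
#' @param ... unused.
#' @return length-T predicted EMG.
#' @export
predict.wiener_cascade <- function(object, latents, ...) {
  if (is.vector(latents)) latents <- matrix(latents, 1)
  stopifnot(nrow(latents) == object$K)
  Z <- cbind(1, lagged_design(latents, object$M))
  y <- as.numeric(Z %*% c(object$intercept, as.vector(t(object$h))))
  object$poly[1] + object$poly[2] * y + object$poly[3] * y^2
}

# Per-fold cross-validated R^2 of a cascade decoder for one EMG channel.
cv_fold_r2 <- function(latents, emg, fold_id, M_lags) {
  folds <- sort(unique(fold_id))
  vapply(folds, function(f) {
    tr <- fold_id != f; te <- !tr
    dec <- fit_wiener_cascade(latents[, tr, drop = FALSE], emg[tr], M_lags)
    pred <- predict(dec, latents[, te, drop = FALSE])
    sst <- sum((emg[te] - mean(emg[te]))^2)
    if (sst <= 0) return(NA_real_)
    1 - sum((emg[te] - pred)^2) / sst
  }, numeric(1))
}

#' Cross-validated, normalized EMG decoding from neural-mode subsets
#'
#' Builds, for one session pooling all tasks, a Wiener-cascade decoder per
#' muscle from a subset of dPCA neural modes (by default the two leading
#' modes of one behavioral parameter), cross-validates it on contiguous
#' 30 s folds (leave-one-fold-out), and normalizes each muscle's R^2 by the
#' R^2 of a decoder using all m modes.
#'
#' @param session a `neural_session`.
#' @param parameter behavioral parameter selecting the input modes
#'   (`"target"`, `"time"`, `"task"`, `"task_target"`), or `"all"` for all
#'   m modes; alternatively pass explicit `mode_subset` indices.
#' @param mode_subset optional explicit mode indices into the dPCA modes.
#' @param n_modes modes per parameter (default 2).
#' @param emg_channels channels to decode (default all).
#' @param fold_seconds fold length (default 30 s).
#' @param m dPCA dimensionality (default 12).
#' @param M_lags filter lags (default 10).
#' @param kernel_sd smoothing s.d. in ms.
#' @param dpca_fit optional precomputed [fit_dpca()] result to reuse.
#' @return class `decoding_result`: data frame `table` (per muscle: raw and
#'   normalized R^2), per-fold matrices `fold_r2` and `fold_r2_all`, and the
#'   mode indices used.
#' @export
crossval_r2 <- function(session, parameter = "target", mode_subset = NULL,
                        n_modes = 2, emg_channels = NULL, fold_seconds = 30,
                        m = 12, M_lags = 10, kernel_sd = 50,
                        dpca_fit = NULL) {
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms, kernel_sd = kernel_sd)
  dp <- dpca_fit %||% fit_dpca(trial_average(rates), m)
  lat <- dpca_latents(dp, rates)
  if (is.null(mode_subset)) {
    if (identical(parameter, "all")) {
      mode_subset <- seq_len(dp$m)
    } else {
      mode_subset <- which(dp$labels == parameter)
      if (length(mode_subset) < n_modes)
        warning("only ", length(mode_subset), " ", parameter,
                "-related modes available")
      mode_subset <- utils::head(mode_subset, n_modes)
      if (!length(mode_subset))
        stop("no modes labeled ", parameter, call. = FALSE)
    }
  }
  env <- emg_envelope(session$emg, session$emg_fs)
  emg <- bin_emg(env, bin_ms = session$bin_ms, n_bins = ncol(lat))
  emg_channels <- emg_channels %||% seq_len(nrow(emg))
  Tn <- ncol(lat)
  fold_bins <- round(fold_seconds * 1000 / session$bin_ms)
  n_folds <- Tn %/% fold_bins
  if (n_folds < 2)
    stop("total duration must cover at least 2 folds", call. = FALSE)
  fold_id <- pmin(((seq_len(Tn) - 1L) %/% fold_bins) + 1L, n_folds)

  sub <- lat[mode_subset, , drop = FALSE]
  fold_r2 <- sapply(emg_channels, function(ch)
    cv_fold_r2(sub, emg[ch, ], fold_id, M_lags))
  fold_r2_all <- sapply(emg_channels, function(ch)
    cv_fold_r2(lat, emg[ch, ], fold_id, M_lags))
  raw <- colMeans(fold_r2, na.rm = TRUE)
  all12 <- colMeans(fold_r2_all, na.rm = TRUE)
  normalized <- ifelse(all12 > 0, raw / all12, NA_real_)
  if (any(all12 <= 0))
    warning("all-mode decoder R^2 <= 0 for some channel(s); ",
            "normalized value undefined, raw value reported")
  structure(list(table = data.frame(muscle = emg_channels, r2 = raw,
                                    r2_all_modes = all12,
                                    r2_normalized = normalized),
                 fold_r2 = fold_r2, fold_r2_all = fold_r2_all,
                 mode_subset = mode_subset, parameter = parameter,
                 dpca = dp),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> parameter %s, modes [%s]\n", x$parameter,
              paste(x$mode_subset, collapse = ", ")))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Demixed PCA of EMG envelopes
#'
#' Applies the same marginalization and reduced-rank machinery as the neural
#' dPCA to the trial structure of the binned EMG envelopes (default m = 4
#' EMG modes).
#'
#' @param emg_binned muscles x T binned EMG envelope matrix.
#' @param trials trial table indexing the columns of `emg_binned`.
#' @param m number of EMG modes (default 4).
#' @param bin_ms bin width in ms.
#' @return a [fit_dpca()] result for the EMG tensor.
#' @export
emg_dpca_modes <- function(emg_binned, trials, m = 4, bin_ms = 20) {
  if (max(abs(emg_binned)) == 0)
    stop("degenerate data: zero EMG", call. = FALSE)
  pseudo <- list(values = emg_binned, trials = trials, bin_ms = bin_ms)
  fit_dpca(trial_average(pseudo), m = min(m, nrow(emg_binned)))
}
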