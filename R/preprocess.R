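#' Smoothed square-root-transformed firing rates
#'
#' Square-root transforms binned spike counts and convolves each unit with a
#' Gaussian kernel (default s.d. 50 ms at 20 ms bins). Smoothing is applied
#' per trial so that no mass bleeds across trial boundaries; the kernel is
#' truncated at +/- 4 s.d. and renormalized to unit mass.
#'
#' @param counts n_units x T nonnegative integer matrix.
#' @param trials optional trial table (`start`/`end` bin columns, as produced
#'   by [generate_session()]); if `NULL` the whole matrix is one trial.
#' @param bin_ms bin width in ms.
#' @param kernel_sd Gaussian kernel s.d. in ms.
#' @return an object of class `rate_matrix`: `values` (n x T), `bin_ms`,
#'   `trials`, and per-unit means in `unit_means`.
#' @export
smooth_rates <- function(counts, trials = NULL, bin_ms = 20, kernel_sd = 50) {
  stopifnot(is.matrix(counts), all(counts >= 0), kernel_sd > 0)
  if (is.null(trials))
    trials <- data.frame(task = 1L, target = 1L, start = 1L,
                         end = ncol(counts), success = TRUE)
  if (any(trials$end < trials$start))
    stop("rejected trial: shorter than 1 bin", call. = FALSE)
  kernel <- gauss_kernel(kernel_sd / bin_ms)
  values <- matrix(0, nrow(counts), ncol(counts))
  root <- sqrt(counts)
  for (i in seq_len(nrow(trials))) {
    idx <- trials$start[i]:trials$end[i]
    sm <- smooth_rows(root[, idx, drop = FALSE], kernel)
    # renormalize by the kernel mass inside the trial so edges are not
    # attenuated (unbiased rate estimate at trial boundaries)
    mass <- as.vector(smooth_rows(matrix(1, 1, length(idx)), kernel))
    values[, idx] <- sweep(sm, 2, mass, `/`)
  }
  structure(list(values = values, bin_ms = bin_ms, trials = trials,
                 unit_means = rowMeans(values)),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d units x %d bins (%d ms), %d trials\n",
              nrow(x$values), ncol(x$values), x$bin_ms, nrow(x$trials)))
  invisible(x)
}

# Zero-phase filtering with odd reflect-padding of 3x the filter order,
# forward and backward passes of the same filter.
zero_phase_filter <- function(filt, x, order) {
  pad <- 3L * order
  if (length(x) <= pad)
    stop("filtering error: fewer samples than 3x filter order",
         call. = FALSE)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  xp <- c(front, x, back)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' EMG envelope extraction
#'
#' Per channel: fourth-order zero-phase Butterworth high-pass at 10 Hz,
#' rectification, fourth-order zero-phase Butterworth low-pass at 50 Hz, then
#' normalization by the channel's 99th percentile pooled over the whole
#' session (all tasks).
#'
#' @param raw muscles x S matrix of raw EMG.
#' @param fs sampling rate in Hz; must exceed 100 Hz.
#' @param hp_hz,lp_hz high-/low-pass corner frequencies.
#' @param percentile normalization percentile (default 99).
#' @return class `emg_envelope`: `values` (muscles x S, normalized),
#'   `norm_consts`, `fs`, and `degenerate` flags for all-zero channels left
#'   unnormalized.
#' @export
emg_envelope <- function(raw, fs, hp_hz = 10, lp_hz = 50, percentile = 99) {
  stopifnot(is.matrix(raw))
  if (fs <= 100) stop("fs must exceed 100 Hz", call. = FALSE)
  hp <- signal::butter(4, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  env <- t(apply(raw, 1, function(x) {
    y <- zero_phase_filter(hp, x, 4L)
    y <- abs(y)
    pmax(zero_phase_filter(lp, y, 4L), 0)
  }))
  norm_consts <- apply(env, 1, stats::quantile, probs = percentile / 100,
                       names = FALSE)
  degenerate <- norm_consts <= 0
  if (any(degenerate))
    warning(sum(degenerate), " all-zero EMG channel(s) left unnormalized")
  scale <- ifelse(degenerate, 1, norm_consts)
  structure(list(values = sweep(env, 1, scale, `/`),
                 norm_consts = norm_consts, fs = fs,
                 degenerate = degenerate),
            class = "emg_envelope")
}

#' Average an EMG envelope into spike-count bins
#'
#' @param env an [emg_envelope()] (or muscles x S matrix with `fs`).
#' @param fs sampling rate (taken from `env` if it is an `emg_envelope`).
#' @param bin_ms bin width in ms.
#' @param n_bins number of output bins (clipped/padded to the available data).
#' @return muscles x n_bins matrix of per-bin mean envelope.
#' @export
bin_emg <- function(env, fs = NULL, bin_ms = 20, n_bins = NULL) {
  vals <- if (inherits(env, "emg_envelope")) env$values else env
  fs <- fs %||% env$fs
  spb <- bin_ms / 1000 * fs
  total <- floor(ncol(vals) / spb)
  n_bins <- min(n_bins %||% total, total)
  out <- matrix(0, nrow(vals), n_bins)
  for (b in seq_len(n_bins)) {
    idx <- (floor((b - 1) * spb) + 1):floor(b * spb)
    out[, b] <- rowMeans(vals[, idx, drop = FALSE])
  }
  out
}

#' Trial-averaged activity tensor
#'
#' Averages single-trial activity across trials of each (task, target)
#' condition. Trials are truncated to the shortest successful trial in the
#' session so that every condition has equal duration; unsuccessful trials
#' are discarded.
#'
#' @param rates a [smooth_rates()] result (or any `rate_matrix`-like object
#'   whose `values` columns are indexed by the trial table).
#' @param trials trial table; defaults to `rates$trials`.
#' @return class `trial_tensor`: `values` array n x alpha x gamma x tau,
#'   `tasks`, `targets`, `tau`, `bin_ms`.
#' @export
trial_average <- function(rates, trials = NULL) {
  trials <- trials %||% rates$trials
  trials <- trials[trials$success, , drop = FALSE]
  tasks <- sort(unique(trials$task))
  targets <- sort(unique(trials$target))
  combos <- expand.grid(task = tasks, target = targets)
  missing <- mapply(function(a, g) !any(trials$task == a & trials$target == g),
                    combos$task, combos$target)
  if (any(missing))
    stop("missing condition(s): ",
         paste(sprintf("(task %s, target %s)", combos$task[missing],
                       combos$target[missing]), collapse = ", "),
         call. = FALSE)
  tau <- min(trials$end - trials$start + 1L)
  n <- nrow(rates$values)
  out <- array(0, c(n, length(tasks), length(targets), tau))
  for (ai in seq_along(tasks)) for (gi in seq_along(targets)) {
    sel <- which(trials$task == tasks[ai] & trials$target == targets[gi])
    acc <- matrix(0, n, tau)
    for (i in sel) {
      idx <- trials$start[i]:(trials$start[i] + tau - 1L)
      acc <- acc + rates$values[, idx, drop = FALSE]
    }
    out[, ai, gi, ] <- acc / length(sel)
  }
  structure(list(values = out, tasks = tasks, targets = targets, tau = tau,
                 bin_ms = rates$bin_ms %||% 20),
            class = "trial_tensor")
}

# Smoothed rates restricted to one task's concatenated trials, with a
# re-indexed trial table (used by per-task PCA and CCA).
task_rates <- function(rates, task) {
  trials <- rates$trials
  sel <- which(trials$task == task & trials$success)
  if (!length(sel)) stop("no trials for task ", task, call. = FALSE)
  cols <- unlist(lapply(sel, function(i) trials$start[i]:trials$end[i]))
  sub <- trials[sel, , drop = FALSE]
  lens <- sub$end - sub$start + 1L
  sub$end <- cumsum(lens)
  sub$start <- c(1L, sub$end[-length(sel)] + 1L)
  sub$go <- sub$start
  structure(list(values = rates$values[, cols, drop = FALSE],
                 bin_ms = rates$bin_ms, trials = sub,
                 task = task,
                 unit_means = rowMeans(rates$values[, cols, drop = FALSE])),
            class = "rate_matrix")
}
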