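# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

# Default synthetic session (shared subspace), reused across test files.
default_session <- function() fixture("default_session", function()
  generate_session(synthetic_config(seed = 42)))

# A small, fast session for plumbing tests.
small_session <- function() fixture("small_session", function()
  generate_session(synthetic_config(
    seed = 7, n_units = 30, n_targets = 2, n_trials_per_condition = 6,
    trial_len = 25, d_time = 2, d_target = 2, d_task = 1, d_tasktarget = 1,
    n_muscles = 4)))

# Deterministic hand-built session: identical "spike" patterns for every
# trial of a condition (no Poisson noise), identical EMG in both task
# blocks. Used for noiseless ceilings and EMG-control identities.
deterministic_session <- function(n_units = 20, n_targets = 2, k_trials = 6,
                                  len = 30) {
  n_tasks <- 2
  patterns <- lapply(seq_len(n_tasks), function(a)
    lapply(seq_len(n_targets), function(g) {
      phase <- a + 2 * g
      t(sapply(seq_len(n_units), function(u)
        pmax(0, round(3 + 2 * sin(2 * pi * (seq_len(len) / len) * (1 + u %% 3)
                                  + phase + u)))))
    }))
  trials <- NULL; cols <- list(); pos <- 0L
  for (a in seq_len(n_tasks)) for (g in seq_len(n_targets))
    for (r in seq_len(k_trials)) {
      trials <- rbind(trials,
                      data.frame(task = a, target = g, start = pos + 1L,
                                 go = pos + 1L, end = pos + len,
                                 success = TRUE))
      cols[[length(cols) + 1L]] <- patterns[[a]][[g]]
      pos <- pos + len
    }
  spikes <- do.call(cbind, cols)
  storage.mode(spikes) <- "integer"
  # EMG: same per-target waveform in both task blocks, at 500 Hz
  fs <- 500; spb <- 20 / 1000 * fs
  S <- ncol(spikes) * spb
  emg <- matrix(0, 4, S)
  for (i in seq_len(nrow(trials))) {
    idx <- ((trials$start[i] - 1) * spb + 1):(trials$end[i] * spb)
    tt <- seq_along(idx) / fs
    for (mch in 1:4)
      emg[mch, idx] <- sin(2 * pi * 30 * tt) *
        (1 + 0.5 * sin(2 * pi * trials$target[i] * tt * 2 + mch) +
           0.3 * sin(2 * pi * (0.7 + 0.3 * mch) * tt * 3 +
                     trials$target[i]))
  }
  structure(list(spikes = spikes, trials = trials, emg = emg,
                 emg_fs = fs, bin_ms = 20),
            class = "neural_session")
}

# Rates matrix with exactly known sample covariance C (k x k) embedded in
# n-dimensional space via the orthonormal basis Q (n x k): sample covariance
# of the result equals Q C t(Q) exactly.
rates_with_covariance <- function(C, Q, T_len = 50) {
  k <- ncol(Q)
  H <- t(stats::poly(seq_len(T_len), k))   # orthonormal, centered rows
  e <- eigen(C, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k) %*% t(e$vectors)
  Q %*% A %*% H * sqrt(T_len - 1)
}
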