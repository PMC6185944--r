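#' Configuration for a synthetic multi-task session
#'
#' Bundles and validates all parameters of the synthetic session generator.
#' The generator plants a low-dimensional set of latent modes shared by the
#' whole recorded population: some modes vary only with time within a trial,
#' some with the target, some with the task, and some with the task/target
#' combination. Population spiking is Poisson around rates driven by these
#' latents; multichannel EMG is a linear readout of the target-related
#' latents plus a task-specific offset and additive noise.
#'
#' @param n_units number of recorded units (population size).
#' @param n_tasks number of tasks in the session.
#' @param n_targets number of targets per task (equalized across tasks).
#' @param n_trials_per_condition successful trials per (task, target) pair.
#' @param trial_len nominal trial length in 20 ms bins (>= 10).
#' @param d_time,d_target,d_task,d_tasktarget number of planted modes whose
#'   trajectories vary only with the named behavioral parameter.
#' @param shared_subspace if `TRUE` every task uses the same loading matrix;
#'   if `FALSE` the loadings of tasks 2..n_tasks are rotated into the
#'   population orthogonal complement by `rotation_angle` degrees.
#' @param rotation_angle planar rotation (degrees) applied to the loadings of
#'   non-shared tasks.
#' @param rotated_modes indices of the planted modes to rotate when
#'   `shared_subspace = FALSE`; default all of them.
#' @param baseline_rate baseline firing rate in events per 20 ms bin.
#' @param latent_sd standard deviation of the planted latent trajectories
#'   (dimensionless, pre-nonlinearity); a scalar, or a vector recycled over
#'   the planted modes to give them distinct variances.
#' @param rate_link `"softplus"` (default; keeps rates positive smoothly) or
#'   `"linear"` (rates clipped at zero, matching a purely linear model).
#' @param n_muscles number of EMG channels.
#' @param snr_emg signal-to-noise variance ratio of the EMG envelope signal.
#' @param emg_fs raw EMG sampling rate in Hz (must exceed 100 Hz so the
#'   envelope filters are well below Nyquist).
#' @param trial_jitter fractional trial-length jitter; trial lengths are drawn
#'   uniformly within `trial_len * (1 +/- trial_jitter)`.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_units = 60, n_tasks = 2, n_targets = 3,
                             n_trials_per_condition = 12, trial_len = 40,
                             d_time = 4, d_target = 4, d_task = 2,
                             d_tasktarget = 2, shared_subspace = TRUE,
                             rotation_angle = 0, rotated_modes = NULL,
                             baseline_rate = 0.3, latent_sd = 4,
                             rate_link = c("softplus", "linear"),
                             n_muscles = 6, snr_emg = 10, emg_fs = 1000,
                             trial_jitter = 0.1, seed = 1L) {
  rate_link <- match.arg(rate_link)
  d <- d_time + d_target + d_task + d_tasktarget
  if (any(c(n_units, n_tasks, n_targets, n_trials_per_condition,
            n_muscles) < 1))
    stop("all counts must be >= 1", call. = FALSE)
  if (any(c(d_time, d_target, d_task, d_tasktarget) < 0) || d < 1)
    stop("mode counts must be >= 0 with at least one planted mode",
         call. = FALSE)
  if (trial_len < 10) stop("trial_len must be >= 10 bins", call. = FALSE)
  if (d > n_units)
    stop("total planted dimensionality (", d, ") exceeds n_units (",
         n_units, ")", call. = FALSE)
  if (!shared_subspace) {
    rotated_modes <- rotated_modes %||% seq_len(d)
    if (any(rotated_modes < 1 | rotated_modes > d))
      stop("rotated_modes out of range", call. = FALSE)
    if (d + length(rotated_modes) > n_units)
      stop("not enough orthogonal complement to rotate ",
           length(rotated_modes), " modes", call. = FALSE)
  }
  if (emg_fs <= 100) stop("emg_fs must exceed 100 Hz", call. = FALSE)
  cfg <- list(n_units = n_units, n_tasks = n_tasks, n_targets = n_targets,
              n_trials_per_condition = n_trials_per_condition,
              trial_len = trial_len, d_time = d_time, d_target = d_target,
              d_task = d_task, d_tasktarget = d_tasktarget, d = d,
              shared_subspace = shared_subspace,
              rotation_angle = rotation_angle, rotated_modes = rotated_modes,
              baseline_rate = baseline_rate, latent_sd = latent_sd,
              rate_link = rate_link, n_muscles = n_muscles,
              snr_emg = snr_emg, emg_fs = emg_fs,
              trial_jitter = trial_jitter, seed = as.integer(seed),
              bin_ms = 20)
  class(cfg) <- "synthetic_config"
  cfg
}

# Smooth random latent trajectory of length tau_max, sd `amp`, mean 0.
smooth_trajectory <- function(tau_max, amp, kernel) {
  x <- as.vector(smooth_rows(matrix(rnorm(tau_max + 2 * length(kernel)), 1),
                             kernel))
  x <- x[(length(kernel) + 1):(length(kernel) + tau_max)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(rep(0, tau_max))
  x / s * amp
}

# Canonical latent trajectories: d x tau_max x n_tasks x n_targets, with each
# mode's trajectory varying only with its labeled behavioral parameter.
# Within a class, mode trajectories are mutually orthogonalized (over the
# flattened condition x time axis) so that each planted mode is an
# identifiable axis of its marginalization, then scaled to its amplitude.
build_latents <- function(cfg, tau_max) {
  d <- cfg$d
  amps <- rep_len(cfg$latent_sd, d)
  kernel <- gauss_kernel(5)  # 100 ms correlation length at 20 ms bins
  L <- array(0, c(d, tau_max, cfg$n_tasks, cfg$n_targets))
  labels <- rep(c("time", "target", "task", "task_target"),
                c(cfg$d_time, cfg$d_target, cfg$d_task, cfg$d_tasktarget))

  orthogonalize <- function(M, amps_class) {
    # Gram-Schmidt over columns, each rescaled to sd = its amplitude
    for (j in seq_len(ncol(M))) {
      v <- M[, j]
      if (j > 1) {
        prev <- M[, seq_len(j - 1), drop = FALSE]
        nrm2 <- colSums(prev^2)
        keep <- nrm2 > .Machine$double.eps
        if (any(keep))
          v <- v - prev[, keep, drop = FALSE] %*%
            (crossprod(prev[, keep, drop = FALSE], v) / nrm2[keep])
      }
      s <- stats::sd(as.vector(v))
      M[, j] <- if (s < .Machine$double.eps) 0 else v / s * amps_class[j]
    }
    M
  }

  idx <- split(seq_len(d), factor(labels, levels = unique(labels)))
  for (lab in names(idx)) {
    js <- idx[[lab]]
    k <- length(js)
    if (lab == "time") {
      M <- sapply(js, function(j) smooth_trajectory(tau_max, 1, kernel))
      M <- orthogonalize(matrix(M, tau_max), amps[js])
      for (q in seq_len(k)) L[js[q], , , ] <- M[, q]
    } else if (lab == "target") {
      # curves per target, centered across targets: no pure-time component
      M <- sapply(js, function(j) {
        A <- sapply(seq_len(cfg$n_targets),
                    function(g) smooth_trajectory(tau_max, 1, kernel))
        as.vector(A - rowMeans(A))
      })
      M <- orthogonalize(matrix(M, tau_max * cfg$n_targets), amps[js])
      for (q in seq_len(k)) {
        A <- matrix(M[, q], tau_max)
        for (g in seq_len(cfg$n_targets)) L[js[q], , , g] <- A[, g]
      }
    } else if (lab == "task") {
      M <- sapply(js, function(j) {
        A <- sapply(seq_len(cfg$n_tasks),
                    function(a) smooth_trajectory(tau_max, 1, kernel))
        as.vector(A - rowMeans(A))
      })
      M <- orthogonalize(matrix(M, tau_max * cfg$n_tasks), amps[js])
      for (q in seq_len(k)) {
        A <- matrix(M[, q], tau_max)
        for (a in seq_len(cfg$n_tasks)) L[js[q], , a, ] <- A[, a]
      }
    } else {
      M <- sapply(js, function(j) {
        A <- array(0, c(tau_max, cfg$n_tasks, cfg$n_targets))
        for (a in seq_len(cfg$n_tasks))
          for (g in seq_len(cfg$n_targets))
            A[, a, g] <- smooth_trajectory(tau_max, 1, kernel)
        # remove task- and target-marginal components (double centering)
        tmean <- apply(A, 1, mean)
        amean <- apply(A, c(1, 2), mean)
        gmean <- apply(A, c(1, 3), mean)
        for (a in seq_len(cfg$n_tasks))
          for (g in seq_len(cfg$n_targets))
            A[, a, g] <- A[, a, g] - amean[, a] - gmean[, g] + tmean
        as.vector(A)
      })
      M <- orthogonalize(matrix(M, tau_max * cfg$n_tasks * cfg$n_targets),
                         amps[js])
      for (q in seq_len(k)) {
        A <- array(M[, q], c(tau_max, cfg$n_tasks, cfg$n_targets))
        for (a in seq_len(cfg$n_tasks)) L[js[q], , a, ] <- A[, a, ]
      }
    }
  }
  list(latents = L, labels = labels, amps = amps)
}

# Per-task loading matrices: shared orthonormal W, or planar rotations of
# selected columns into the population orthogonal complement.
build_loadings <- function(cfg) {
  n <- cfg$n_units
  d <- cfg$d
  W <- random_orthonormal(n, n)  # full basis: first d = loadings, rest = complement
  W0 <- W[, seq_len(d), drop = FALSE]
  loadings <- vector("list", cfg$n_tasks)
  loadings[[1]] <- W0
  theta <- cfg$rotation_angle * pi / 180
  for (a in seq_len(cfg$n_tasks)[-1]) {
    if (cfg$shared_subspace || theta == 0) {
      loadings[[a]] <- W0
    } else {
      Wa <- W0
      for (i in seq_along(cfg$rotated_modes)) {
        j <- cfg$rotated_modes[i]
        v <- W[, d + i]
        Wa[, j] <- cos(theta) * W0[, j] + sin(theta) * v
      }
      loadings[[a]] <- Wa
    }
  }
  loadings
}

#' Generate a synthetic multi-task session with planted ground truth
#'
#' Draws a session of binned spike counts, trial metadata, and raw multichannel
#' EMG from a known low-dimensional generative model (see
#' [synthetic_config()]). Unit rates are
#' `link(b0 + W %*% latents)` per 20 ms bin, with independent Poisson counts;
#' `b0` is set so that a silent latent state yields `baseline_rate`. EMG
#' envelopes are `emg_mixing %*% target_latents + task_offset + noise`
#' (rectified at zero), and the raw EMG is carrier white noise at `emg_fs`
#' amplitude-modulated by that envelope.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `session` (class `neural_session`: `spikes`
#'   n_units x T integer matrix, `trials` data frame, `emg` muscles x S raw
#'   EMG matrix, `emg_fs`, `bin_ms`) and `truth` (class
#'   `synthetic_ground_truth`: per-task loadings, canonical latent
#'   trajectories, mode labels, EMG mixing, clean binned envelopes, config).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    tau_max <- ceiling(cfg$trial_len * (1 + cfg$trial_jitter))
    lat <- build_latents(cfg, tau_max)
    loadings <- build_loadings(cfg)
    b0 <- inv_softplus(cfg$baseline_rate)

    # trial lengths and ordering: tasks in blocks, targets interleaved
    trials <- do.call(rbind, lapply(seq_len(cfg$n_tasks), function(a) {
      tg <- rep(seq_len(cfg$n_targets), cfg$n_trials_per_condition)
      tg <- sample(tg)
      data.frame(task = a, target = tg)
    }))
    n_trials <- nrow(trials)
    lens <- if (cfg$trial_jitter > 0) {
      pmin(tau_max, pmax(10L, round(cfg$trial_len *
        stats::runif(n_trials, 1 - cfg$trial_jitter, 1 + cfg$trial_jitter))))
    } else rep(cfg$trial_len, n_trials)
    ends <- cumsum(lens)
    starts <- c(1L, ends[-length(ends)] + 1L)
    trials$start <- starts
    trials$go <- starts
    trials$end <- ends
    trials$success <- TRUE
    Tn <- sum(lens)

    spikes <- matrix(0L, cfg$n_units, Tn)
    emg_env <- matrix(0, cfg$n_muscles, Tn)
    emg_mixing <- matrix(stats::runif(cfg$n_muscles * max(cfg$d_target, 1),
                                      -1, 1),
                         cfg$n_muscles)
    muscle_base <- stats::runif(cfg$n_muscles, 0.5, 1.5)
    task_offsets <- matrix(stats::runif(cfg$n_muscles * cfg$n_tasks,
                                        -0.3, 0.3),
                           cfg$n_muscles)
    target_rows <- which(lat$labels == "target")

    for (i in seq_len(n_trials)) {
      a <- trials$task[i]; g <- trials$target[i]
      idx <- trials$start[i]:trials$end[i]
      Ltr <- lat$latents[, seq_along(idx), a, g, drop = FALSE]
      dim(Ltr) <- c(cfg$d, length(idx))
      eta <- b0 + loadings[[a]] %*% Ltr
      lambda <- if (cfg$rate_link == "softplus") softplus(eta) else pmax(eta, 0)
      spikes[, idx] <- matrix(stats::rpois(length(lambda), lambda),
                              cfg$n_units)
      env <- muscle_base + task_offsets[, a] +
        if (length(target_rows)) {
          scl <- pmax(lat$amps[target_rows], .Machine$double.eps)
          emg_mixing %*% (Ltr[target_rows, , drop = FALSE] / scl)
        } else 0
      emg_env[, idx] <- env
    }
    sig_var <- apply(emg_env, 1, stats::var)
    noise_sd <- sqrt(pmax(sig_var, 1e-12) / cfg$snr_emg)
    clean_env <- pmax(emg_env, 0)
    emg_env <- emg_env + matrix(stats::rnorm(length(emg_env)),
                                cfg$n_muscles) * noise_sd
    emg_env <- pmax(emg_env, 0)

    # raw EMG: envelope (linearly interpolated to emg_fs) modulating a
    # white-noise carrier
    spb <- cfg$bin_ms / 1000 * cfg$emg_fs   # samples per bin
    S <- round(Tn * spb)
    bin_time <- (seq_len(Tn) - 0.5) * cfg$bin_ms / 1000
    samp_time <- (seq_len(S) - 0.5) / cfg$emg_fs
    emg_raw <- matrix(0, cfg$n_muscles, S)
    for (mch in seq_len(cfg$n_muscles)) {
      ev <- stats::approx(bin_time, emg_env[mch, ], xout = samp_time,
                          rule = 2)$y
      emg_raw[mch, ] <- ev * stats::rnorm(S)
    }

    session <- structure(list(spikes = spikes, trials = trials,
                              emg = emg_raw, emg_fs = cfg$emg_fs,
                              bin_ms = cfg$bin_ms),
                         class = "neural_session")
    truth <- structure(list(loadings = loadings,
                            W = loadings[[1]],
                            latents = lat$latents,
                            mode_labels = lat$labels,
                            emg_mixing = emg_mixing,
                            muscle_base = muscle_base,
                            task_offsets = task_offsets,
                            emg_env_clean = clean_env,
                            config = cfg),
                        class = "synthetic_ground_truth")
    list(session = session, truth = truth)
  })
}

#' @export
print.neural_session <- function(x, ...) {
  cat("<neural_session>\n")
  cat(sprintf("  %d units x %d bins (%d ms bins), %d trials\n",
              nrow(x$spikes), ncol(x$spikes), x$bin_ms, nrow(x$trials)))
  cat(sprintf("  tasks: %s; targets: %s\n",
              paste(sort(unique(x$trials$task)), collapse = ", "),
              paste(sort(unique(x$trials$target)), collapse = ", ")))
  cat(sprintf("  EMG: %d channels at %g Hz\n", nrow(x$emg), x$emg_fs))
  invisible(x)
}

#' Exact principal angles between planted task subspaces
#'
#' Returns the principal angles (degrees, ascending) between the planted
#' loading subspaces of two tasks of a synthetic session, computed directly
#' from the known orthonormal bases. Used as the recovery target for
#' estimated angles.
#'
#' @param truth a `synthetic_ground_truth`.
#' @param task_a,task_b task indices.
#' @return numeric vector of `d` angles in degrees, ascending.
#' @export
planted_principal_angles <- function(truth, task_a, task_b) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  n_tasks <- length(truth$loadings)
  if (task_a < 1 || task_a > n_tasks || task_b < 1 || task_b > n_tasks)
    stop("unknown task label", call. = FALSE)
  Wa <- truth$loadings[[task_a]]
  Wb <- truth$loadings[[task_b]]
  s <- svd(crossprod(Wa, Wb), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, 0), 1)) * 180 / pi)
}
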