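#' Simulate a neural population driven only by EMG
#'
#' Null model for manifold and latent-activity comparisons: each simulated
#' unit is a Poisson process whose time-dependent mean is a fixed affine
#' function of the recorded EMG envelopes,
#' `lambda_j(t) = a_j + sum_i b_ji * eps_i(t) + eta_j(t)` with
#' `a_j ~ U[0, 0.1]`, `b_ji ~ U[-1, 1]`, and Gaussian noise of variance
#' 0.05. Rates are rectified at zero and then scaled multiplicatively per
#' unit so their time-mean matches the corresponding target mean rate.
#'
#' @param emg muscles x T matrix of normalized EMG envelopes at the spike
#'   bin width (e.g. [bin_emg()] output), or an [emg_envelope()] plus
#'   binning done by the caller.
#' @param n_units number of units to simulate (match the recorded count).
#' @param target_mean_rates length-n_units vector of mean rates in events
#'   per bin to match (recycled if scalar).
#' @param seed integer seed.
#' @param noise_var variance of the additive Gaussian noise (default 0.05).
#' @param a_max upper bound of the uniform offsets `a_j` (default 0.1).
#' @param trials optional trial table to attach to the returned session.
#' @param bin_ms bin width in ms.
#' @return a `neural_session` (spikes only; `emg` carries the driving
#'   envelopes) with attribute `model` (class `emg_sim_model`: the sampled
#'   `a`, `b`, per-unit `scale`, and the scaled rate matrix `lambda`).
#' @export
simulate_population <- function(emg, n_units, target_mean_rates, seed = 1L,
                                noise_var = 0.05, a_max = 0.1,
                                trials = NULL, bin_ms = 20) {
  stopifnot(is.matrix(emg), n_units >= 1)
  target <- rep_len(target_mean_rates, n_units)
  with_seed(seed, {
    n_mus <- nrow(emg); Tn <- ncol(emg)
    a <- stats::runif(n_units, 0, a_max)
    b <- matrix(stats::runif(n_units * n_mus, -1, 1), n_units)
    lambda <- a + b %*% emg
    if (noise_var > 0)
      lambda <- lambda + matrix(stats::rnorm(n_units * Tn,
                                             sd = sqrt(noise_var)), n_units)
    lambda_linear <- lambda          # affine stage: rank <= n_muscles + 1
    lambda <- pmax(lambda, 0)
    mr <- rowMeans(lambda)
    zero_rate <- mr <= 0
    if (any(zero_rate))
      message(sum(zero_rate), " unit(s) have zero rate; left silent")
    scale <- ifelse(zero_rate, 0, target / pmax(mr, .Machine$double.eps))
    lambda <- lambda * scale
    spikes <- matrix(stats::rpois(length(lambda), lambda), n_units)
    sess <- structure(list(spikes = spikes, trials = trials, emg = emg,
                           emg_fs = 1000 / bin_ms, bin_ms = bin_ms),
                      class = "neural_session")
    attr(sess, "model") <- structure(list(a = a, b = b, scale = scale,
                                          lambda = lambda,
                                          lambda_linear = lambda_linear,
                                          noise_var = noise_var,
                                          seed = seed),
                                     class = "emg_sim_model")
    sess
  })
}

#' Compare a recorded session to its EMG-driven simulation
#'
#' Runs the manifold and latent-comparison pipelines identically on a
#' "real" session and on an EMG-simulated session: per-task cumulative PCA
#' VAF curves, and across-task canonical correlations between the two
#' tasks' latent activities, for both sessions, plus the per-rank ratio of
#' real to simulated CCs.
#'
#' @param real_session,sim_session two `neural_session`s with identical
#'   trial structure.
#' @param task_pair the two task labels to compare.
#' @param m manifold dimensionality.
#' @param window_ms CCA window length (ms).
#' @param kernel_sd smoothing s.d. (ms).
#' @return list with `vaf_real`, `vaf_sim` (per-task cumulative VAF
#'   matrices, modes x tasks), `cc_real`, `cc_sim`, and `cc_ratio`.
#' @export
null_model_comparison <- function(real_session, sim_session,
                                  task_pair = c(1, 2), m = 12,
                                  window_ms = 600, kernel_sd = 50) {
  vaf_curves <- function(sess) {
    rates <- smooth_rates(sess$spikes, sess$trials, bin_ms = sess$bin_ms,
                          kernel_sd = kernel_sd)
    sapply(task_pair, function(a) {
      mani <- fit_pca(task_rates(rates, a), m)
      cumsum(mani$eigenvalues[seq_len(m)]) / sum(mani$eigenvalues)
    })
  }
  ccs <- function(sess) {
    mm <- match_and_concat(sess, task_pair[1], task_pair[2],
                           window_ms = window_ms, m = m,
                           kernel_sd = kernel_sd)
    cca(mm$L_a, mm$L_b)$correlations
  }
  cc_real <- ccs(real_session)
  cc_sim <- ccs(sim_session)
  list(vaf_real = vaf_curves(real_session),
       vaf_sim = vaf_curves(sim_session),
       cc_real = cc_real, cc_sim = cc_sim,
       cc_ratio = cc_real / pmax(cc_sim, .Machine$double.eps))
}
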