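#' Analysis configuration
#'
#' Collects every tunable parameter of the full-session analysis with the
#' standard defaults: 20 ms bins, 50 ms smoothing kernel, m = 12 manifold
#' dimensions (sweep 8/12/15), 0.1th-percentile significance against
#' surrogates, 700 ms CCA windows, 30 s decoding folds. Surrogate and
#' bootstrap counts default to desk-scale values (1000 / 500); set
#' `full_scale = TRUE` for the 10000-surrogate / 5000-bootstrap analysis.
#'
#' @param m manifold dimensionality.
#' @param m_sweep dimensionalities for the robustness sweep.
#' @param kernel_sd smoothing kernel s.d. (ms).
#' @param window_ms CCA window (ms).
#' @param n_surrogates,n_boot,n_ceiling_reps,n_random_manifolds Monte Carlo
#'   sizes.
#' @param alpha significance level for principal angles.
#' @param fold_seconds decoding fold length (s).
#' @param M_lags decoder filter lags (bins).
#' @param drop_fractions unit-dropping fractions.
#' @param n_drop_pairs random pairs per dropping fraction.
#' @param full_scale use 10000 surrogates and 5000 bootstraps.
#' @param seed master seed; stages draw from offset substreams.
#' @return class `analysis_config`.
#' @export
analysis_config <- function(m = 12, m_sweep = c(8, 12, 15), kernel_sd = 50,
                            window_ms = 700, n_surrogates = 1000,
                            n_boot = 500, n_ceiling_reps = 100,
                            n_random_manifolds = 1000, alpha = 0.001,
                            fold_seconds = 30, M_lags = 10,
                            drop_fractions = c(0.1, 0.2, 0.3, 0.4),
                            n_drop_pairs = 100, full_scale = FALSE,
                            seed = 1L) {
  if (full_scale) {
    n_surrogates <- 10000
    n_boot <- 5000
    n_random_manifolds <- 10000
  }
  stopifnot(all(c(m, m_sweep, n_surrogates, n_boot, n_ceiling_reps,
                  n_random_manifolds, M_lags) >= 1))
  structure(list(m = m, m_sweep = m_sweep, kernel_sd = kernel_sd,
                 window_ms = window_ms, n_surrogates = n_surrogates,
                 n_boot = n_boot, n_ceiling_reps = n_ceiling_reps,
                 n_random_manifolds = n_random_manifolds, alpha = alpha,
                 fold_seconds = fold_seconds, M_lags = M_lags,
                 drop_fractions = drop_fractions,
                 n_drop_pairs = n_drop_pairs, seed = as.integer(seed)),
            class = "analysis_config")
}

run_stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch(
    list(ok = TRUE, result = force(expr)),
    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  report
}

#' Run the full multi-task session analysis
#'
#' Sequences the whole pipeline on one session: preprocessing, per-task
#' manifolds, all pairwise principal-angle comparisons with surrogate
#' significance, across-task VAF ratios with random-manifold chance bounds,
#' CCA latent comparisons with within-task ceilings and bootstrap nulls,
#' dPCA with per-parameter VAF, and EMG decoding from parameter-specific
#' mode subsets. Stages that fail are flagged in the report rather than
#' aborting the run; everything is deterministic given `config$seed`.
#'
#' @param session a `neural_session`.
#' @param config an [analysis_config()].
#' @param stages character vector selecting stages (default all):
#'   `"angles"`, `"vaf"`, `"cca"`, `"dpca"`, `"decoding"`.
#' @return class `session_report`.
#' @export
run_full_analysis <- function(session, config = analysis_config(),
                              stages = c("angles", "vaf", "cca", "dpca",
                                         "decoding")) {
  cfg <- config
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms,
                        kernel_sd = cfg$kernel_sd)
  tasks <- sort(unique(session$trials$task))
  manifolds <- lapply(tasks, function(a) fit_pca(task_rates(rates, a), cfg$m))
  names(manifolds) <- as.character(tasks)
  report <- structure(list(tasks = tasks, config = cfg, manifolds = manifolds,
                           stages = list()),
                      class = "session_report")
  pairs <- if (length(tasks) >= 2) utils::combn(tasks, 2, simplify = FALSE)
           else list()
  tensor <- if (length(tasks) >= 1) trial_average(rates) else NULL

  if ("angles" %in% stages && length(pairs))
    report <- run_stage(report, "angles", with_seed(cfg$seed + 1L, {
      lapply(pairs, function(p) {
        ia <- match(p[1], tasks); ib <- match(p[2], tasks)
        pa <- principal_angles(manifolds[[ia]], manifolds[[ib]])
        ens <- tme_surrogates(tensor, n_surrogates = cfg$n_surrogates,
                              m = cfg$m, tasks = c(ia, ib))
        sig <- angle_significance(pa, ens, cfg$alpha)
        list(pair = p, angles = pa$angles, thresholds = sig$thresholds,
             k_significant = sig$k)
      })
    }))

  if ("vaf" %in% stages && length(pairs))
    report <- run_stage(report, "vaf", with_seed(cfg$seed + 2L, {
      lapply(pairs, function(p) {
        ia <- match(p[1], tasks); ib <- match(p[2], tasks)
        ra <- task_rates(rates, p[1]); rb <- task_rates(rates, p[2])
        ctrl <- random_manifold_control(ra, cfg$m,
                                        n_draws = cfg$n_random_manifolds)
        list(pair = p,
             ratio_ab = across_task_vaf_ratio(ra, manifolds[[ia]],
                                              manifolds[[ib]]),
             ratio_ba = across_task_vaf_ratio(rb, manifolds[[ib]],
                                              manifolds[[ia]]),
             chance_ratio = ctrl$ratio_threshold)
      })
    }))

  if ("cca" %in% stages && length(pairs))
    report <- run_stage(report, "cca", with_seed(cfg$seed + 3L, {
      lapply(pairs, function(p) {
        mm <- match_and_concat(session, p[1], p[2],
                               window_ms = cfg$window_ms, m = cfg$m,
                               kernel_sd = cfg$kernel_sd)
        cc <- cca(mm$L_a, mm$L_b)
        ceil_a <- within_task_ceiling(session, p[1],
                                      n_reps = cfg$n_ceiling_reps,
                                      window_ms = cfg$window_ms, m = cfg$m,
                                      kernel_sd = cfg$kernel_sd,
                                      probs = 1 - cfg$alpha)
        ceil_b <- within_task_ceiling(session, p[2],
                                      n_reps = cfg$n_ceiling_reps,
                                      window_ms = cfg$window_ms, m = cfg$m,
                                      kernel_sd = cfg$kernel_sd,
                                      probs = 1 - cfg$alpha)
        null <- bootstrap_null(mm$L_a, mm$L_b, n_boot = cfg$n_boot,
                               kernel_sd = cfg$kernel_sd,
                               bin_ms = session$bin_ms,
                               probs = 1 - cfg$alpha)
        list(pair = p, correlations = cc$correlations,
             ceiling = pmax(ceil_a$ceiling, ceil_b$ceiling),
             null_threshold = null$threshold,
             n_significant = sum(cc$correlations > null$threshold))
      })
    }))

  if ("dpca" %in% stages && !is.null(tensor))
    report <- run_stage(report, "dpca", {
      dp <- fit_dpca(tensor, cfg$m)
      pca_curve <- dpca_vaf(tensor, t(pca_basis(unfold_tensor(
        tensor$values), cfg$m)), pca_basis(unfold_tensor(tensor$values),
                                           cfg$m))
      list(fit = dp, parameter_vaf = label_modes(dp)$parameter_vaf,
           vaf_curve = dpca_vaf(tensor, dp$encoder, dp$decoder),
           pca_vaf_curve = pca_curve)
    })

  if ("decoding" %in% stages)
    report <- run_stage(report, "decoding", with_seed(cfg$seed + 4L, {
      dp <- if (!is.null(report$stages$dpca) && report$stages$dpca$ok)
        report$stages$dpca$result$fit else NULL
      params <- c("target", "time", "task", "task_target")
      res <- lapply(params, function(p)
        tryCatch(crossval_r2(session, parameter = p,
                             fold_seconds = cfg$fold_seconds, m = cfg$m,
                             M_lags = cfg$M_lags,
                             kernel_sd = cfg$kernel_sd, dpca_fit = dp),
                 error = function(e) NULL))
      names(res) <- params
      res
    }))
  report
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d task(s); stages: %s\n",
              length(x$tasks),
              paste(names(x$stages), collapse = ", ")))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    if (!st$ok) {
      cat(sprintf("  %s: FAILED (%s)\n", nm, st$error))
    } else if (nm == "angles") {
      for (r in st$result)
        cat(sprintf("  angles %s-%s: k = %d of %d significantly small\n",
                    r$pair[1], r$pair[2], r$k_significant,
                    length(r$angles)))
    } else if (nm == "vaf") {
      for (r in st$result)
        cat(sprintf("  VAF ratio %s-%s: %.2f / %.2f (chance %.2f)\n",
                    r$pair[1], r$pair[2], r$ratio_ab, r$ratio_ba,
                    r$chance_ratio))
    } else if (nm == "cca") {
      for (r in st$result)
        cat(sprintf("  CCA %s-%s: leading CC %.2f, %d above null\n",
                    r$pair[1], r$pair[2], r$correlations[1],
                    r$n_significant))
    } else if (nm == "dpca") {
      cat(sprintf("  dPCA total VAF %.1f%%\n",
                  100 * st$result$fit$total_vaf))
    } else if (nm == "decoding") {
      for (p in names(st$result)) if (!is.null(st$result[[p]]))
        cat(sprintf("  decoding (%s): mean normalized R2 %.2f\n", p,
                    mean(st$result[[p]]$table$r2_normalized, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' Unit-dropping robustness control
#'
#' For each dropping fraction, repeatedly (1) zeroes two disjoint random
#' unit subsets and compares the two resulting m-dimensional manifolds by
#' principal angles within the original embedding space (orientation
#' robustness), and (2) zeroes one random subset and compares its latent
#' activity to the full-population latents with CCA (latent robustness).
#'
#' @param session a `neural_session`.
#' @param task task label to analyze (default first).
#' @param drop_fractions fractions of units to drop.
#' @param n_pairs random pairs per fraction (default 100).
#' @param m manifold dimensionality.
#' @param kernel_sd smoothing s.d. (ms).
#' @param seed seed.
#' @return list per fraction with `angles` (n_pairs x m) and `ccs`
#'   (n_pairs x m); fractions leaving fewer than m active units are skipped
#'   with a message.
#' @export
unit_dropping_control <- function(session, task = NULL,
                                  drop_fractions = c(0.1, 0.2, 0.3, 0.4),
                                  n_pairs = 100, m = 12, kernel_sd = 50,
                                  seed = 1L) {
  task <- task %||% sort(unique(session$trials$task))[1]
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms, kernel_sd = kernel_sd)
  rt <- task_rates(rates, task)
  n <- nrow(rt$values)
  full_mani <- fit_pca(rt, m)
  full_lat <- project(rt, full_mani)$values
  with_seed(seed, {
    out <- lapply(drop_fractions, function(f) {
      nd <- round(f * n)
      if (n - nd < m) {
        message("fraction ", f, " leaves fewer than m units; skipped")
        return(NULL)
      }
      angles <- matrix(0, n_pairs, m)
      ccs <- matrix(0, n_pairs, m)
      for (i in seq_len(n_pairs)) {
        drop2 <- sample.int(n, 2 * nd)
        X1 <- rt$values; X1[drop2[seq_len(nd)], ] <- 0
        X2 <- rt$values; X2[drop2[nd + seq_len(nd)], ] <- 0
        m1 <- fit_pca(X1, m); m2 <- fit_pca(X2, m)
        angles[i, ] <- angles_between(m1$W, m2$W)
        if (f > 0) {
          Xd <- rt$values; Xd[drop2[seq_len(nd)], ] <- 0
          md <- fit_pca(Xd, m)
          lat_d <- crossprod(md$W, Xd - md$mean)
          ccs[i, ] <- cca(lat_d, full_lat)$correlations
        } else {
          ccs[i, ] <- 1
        }
      }
      list(fraction = f, angles = angles, ccs = ccs)
    })
    names(out) <- paste0("drop_", drop_fractions)
    out[!vapply(out, is.null, TRUE)]
  })
}

#' Dimensionality sweep of the principal-angle analysis
#'
#' Repeats the pairwise principal-angle significance analysis at several
#' manifold dimensionalities (default 8, 12, 15), reusing one surrogate
#' ensemble whose manifolds are stored up to the largest m.
#'
#' @param session a `neural_session`.
#' @param m_values dimensionalities to test.
#' @param task_pair the two task labels.
#' @param n_surrogates surrogate pairs.
#' @param kernel_sd smoothing s.d. (ms).
#' @param alpha significance level.
#' @param seed seed.
#' @return data frame: per m, the count `k` of leading significantly small
#'   angles.
#' @export
dimensionality_sweep <- function(session, m_values = c(8, 12, 15),
                                 task_pair = c(1, 2), n_surrogates = 1000,
                                 kernel_sd = 50, alpha = 0.001, seed = 1L) {
  rates <- smooth_rates(session$spikes, session$trials,
                        bin_ms = session$bin_ms, kernel_sd = kernel_sd)
  if (max(m_values) > nrow(session$spikes))
    stop("m exceeds the number of units", call. = FALSE)
  tensor <- trial_average(rates)
  ia <- match(task_pair[1], tensor$tasks)
  ib <- match(task_pair[2], tensor$tasks)
  ens <- with_seed(seed, tme_surrogates(tensor, n_surrogates = n_surrogates,
                                        m = m_values, tasks = c(ia, ib)))
  ra <- task_rates(rates, task_pair[1])
  rb <- task_rates(rates, task_pair[2])
  mani_a <- fit_pca(ra, max(m_values))
  mani_b <- fit_pca(rb, max(m_values))
  rows <- lapply(m_values, function(mm) {
    ang <- angles_between(mani_a$W[, seq_len(mm), drop = FALSE],
                          mani_b$W[, seq_len(mm), drop = FALSE])
    sig <- angle_significance(ang, ens, alpha)
    data.frame(m = mm, k_significant = sig$k,
               leading_angle = ang[1], largest_angle = ang[mm])
  })
  do.call(rbind, rows)
}

#' EMG manifold and latent-activity control
#'
#' Applies the same manifold comparison machinery to the muscle activity:
#' per-task PCA of binned EMG envelopes (default 4-D), principal angles
#' between task EMG manifolds with surrogate thresholds, CCA of latent
#' muscle activity across tasks, and the ratio of neural to EMG canonical
#' correlations.
#'
#' @param session a `neural_session` with >= 4 EMG channels (fewer reduces
#'   m with a warning).
#' @param task_pair the two task labels.
#' @param m_emg EMG manifold dimensionality (default 4).
#' @param m_neural neural manifold dimensionality for the CC ratio.
#' @param window_ms CCA window (ms).
#' @param n_surrogates surrogate pairs for angle significance.
#' @param kernel_sd neural smoothing s.d. (ms).
#' @param alpha significance level.
#' @param seed seed.
#' @return list with EMG `angles`, `thresholds`, `k_significant`, `cc_emg`,
#'   `cc_neural`, and `cc_ratio` (neural / EMG per rank).
#' @export
emg_manifold_control <- function(session, task_pair = c(1, 2), m_emg = 4,
                                 m_neural = 12, window_ms = 700,
                                 n_surrogates = 1000, kernel_sd = 50,
                                 alpha = 0.001, seed = 1L) {
  n_mus <- nrow(session$emg)
  if (n_mus < m_emg) {
    warning("only ", n_mus, " EMG channels; reducing m to ", n_mus)
    m_emg <- n_mus
  }
  env <- emg_envelope(session$emg, session$emg_fs)
  emg_binned <- bin_emg(env, bin_ms = session$bin_ms,
                        n_bins = ncol(session$spikes))
  emg_rates <- list(values = emg_binned, trials = session$trials,
                    bin_ms = session$bin_ms)
  tasks <- sort(unique(session$trials$task))
  ea <- task_rates(emg_rates, task_pair[1])
  eb <- task_rates(emg_rates, task_pair[2])
  mani_a <- fit_pca(ea, m_emg)
  mani_b <- fit_pca(eb, m_emg)
  ang <- principal_angles(mani_a, mani_b)
  tensor <- trial_average(emg_rates)
  ens <- with_seed(seed, tme_surrogates(
    tensor, n_surrogates = n_surrogates, m = m_emg,
    tasks = c(match(task_pair[1], tensor$tasks),
              match(task_pair[2], tensor$tasks))))
  sig <- angle_significance(ang, ens, alpha)
  mm_emg <- match_core(emg_rates, task_pair[1], task_pair[2],
                       window_ms = window_ms, m = m_emg,
                       bin_ms = session$bin_ms)
  cc_emg <- cca(mm_emg$L_a, mm_emg$L_b)$correlations
  mm_neur <- match_and_concat(session, task_pair[1], task_pair[2],
                              window_ms = window_ms, m = m_neural,
                              kernel_sd = kernel_sd)
  cc_neural <- cca(mm_neur$L_a, mm_neur$L_b)$correlations
  nr <- min(length(cc_emg), length(cc_neural))
  list(angles = ang$angles, thresholds = sig$thresholds,
       k_significant = sig$k, cc_emg = cc_emg, cc_neural = cc_neural,
       cc_ratio = cc_neural[seq_len(nr)] / pmax(cc_emg[seq_len(nr)],
                                                .Machine$double.eps))
}
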