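test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(n_units = 13, d_time = 4, d_target = 4,
                                d_task = 2, d_tasktarget = 2,
                                shared_subspace = FALSE,
                                rotation_angle = 30),
               "orthogonal complement")
  expect_error(synthetic_config(n_units = 5, d_time = 4, d_target = 4,
                                d_task = 2, d_tasktarget = 2),
               "exceeds n_units")
  expect_error(synthetic_config(trial_len = 5), "trial_len")
  expect_error(synthetic_config(emg_fs = 50), "emg_fs")
})

test_that("silent configuration yields an all-zero population", {
  gs <- generate_session(synthetic_config(seed = 1, latent_sd = 0,
                                          baseline_rate = 0,
                                          n_units = 20, trial_len = 15,
                                          n_trials_per_condition = 2))
  expect_true(all(gs$session$spikes == 0))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 99, n_units = 25, trial_len = 20,
                          n_trials_per_condition = 3)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1$session$spikes, g2$session$spikes)
  expect_identical(g1$session$emg, g2$session$emg)
  expect_identical(g1$session$trials, g2$session$trials)
  g3 <- generate_session(synthetic_config(seed = 100, n_units = 25,
                                          trial_len = 20,
                                          n_trials_per_condition = 3))
  expect_false(identical(g1$session$spikes, g3$session$spikes))
})

test_that("empirical mean rates match the intended softplus rates", {
  cfg <- synthetic_config(seed = 3, n_units = 60, n_tasks = 3,
                          trial_jitter = 0, n_trials_per_condition = 10)
  gs <- generate_session(cfg)
  s <- gs$session; tr <- gs$truth
  b0 <- neuromodes:::inv_softplus(cfg$baseline_rate)
  # with no jitter all trials of a condition are identical: accumulate the
  # intended rate bin by bin
  lam_sum <- numeric(cfg$n_units)
  for (i in seq_len(nrow(s$trials))) {
    a <- s$trials$task[i]; g <- s$trials$target[i]
    len <- s$trials$end[i] - s$trials$start[i] + 1L
    L <- matrix(tr$latents[, seq_len(len), a, g], nrow = cfg$d)
    lam_sum <- lam_sum +
      rowSums(neuromodes:::softplus(b0 + tr$loadings[[a]] %*% L))
  }
  Tn <- ncol(s$spikes)
  intended_mean <- lam_sum / Tn
  se <- sqrt(lam_sum) / Tn          # Poisson s.e. of the mean over T bins
  observed <- rowMeans(s$spikes)
  expect_true(all(abs(observed - intended_mean) <= 3 * se + 1e-12))
})

test_that("planted trajectories vary only with their labeled parameter", {
  gs <- default_session()
  lat <- gs$truth$latents
  labs <- gs$truth$mode_labels
  for (j in which(labs == "time"))
    for (a in 1:2) for (g in 1:3)
      expect_equal(lat[j, , a, g], lat[j, , 1, 1])
  for (j in which(labs == "target")) {
    expect_equal(lat[j, , 1, 2], lat[j, , 2, 2])   # same across tasks
    expect_gt(max(abs(lat[j, , 1, 1] - lat[j, , 1, 2])), 1e-8)
  }
  for (j in which(labs == "task")) {
    expect_equal(lat[j, , 2, 1], lat[j, , 2, 3])   # same across targets
    expect_gt(max(abs(lat[j, , 1, 1] - lat[j, , 2, 1])), 1e-8)
  }
})

test_that("planted loadings are orthonormal and planted angles exact", {
  gs <- default_session()
  for (Wa in gs$truth$loadings)
    expect_lt(max(abs(crossprod(Wa) - diag(ncol(Wa)))), 1e-10)
  expect_lt(max(planted_principal_angles(gs$truth, 1, 2)), 1e-5)
  expect_error(planted_principal_angles(gs$truth, 1, 5), "unknown task")

  rot <- generate_session(synthetic_config(
    seed = 5, shared_subspace = FALSE, rotation_angle = 30,
    rotated_modes = 12, n_trials_per_condition = 2, trial_len = 15))
  ang <- planted_principal_angles(rot$truth, 1, 2)
  expect_lt(max(abs(ang - c(rep(0, 11), 30))), 1e-5)

  rot_all <- generate_session(synthetic_config(
    seed = 6, shared_subspace = FALSE, rotation_angle = 55,
    n_trials_per_condition = 2, trial_len = 15))
  set.seed(1)
  expect_equal(planted_principal_angles(rot_all$truth, 1, 2),
               oracle_principal_angles(rot_all$truth$loadings[[1]],
                                       rot_all$truth$loadings[[2]]),
               tolerance = 1e-6)
})

test_that("session container round-trips through the CSV layout", {
  gs <- small_session()
  dir <- withr::local_tempdir()
  write_session(gs$session, dir)
  back <- read_session(dir)
  expect_identical(back$spikes, gs$session$spikes)
  expect_equal(back$emg, gs$session$emg, tolerance = 1e-12)
  expect_equal(back$trials$start, gs$session$trials$start)
  expect_equal(back$bin_ms, gs$session$bin_ms)

  cfg <- synthetic_config(seed = 11, n_targets = 4, snr_emg = 5)
  path <- file.path(dir, "cfg.yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
})
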