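make_tensor <- function(values, tasks = NULL, targets = NULL) {
  dn <- dim(values)
  structure(list(values = values, tasks = tasks %||% seq_len(dn[2]),
                 targets = targets %||% seq_len(dn[3]), tau = dn[4],
                 bin_ms = 20),
            class = "trial_tensor")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marginalization is exact, demixed, and matches the loop oracle", {
  # constant tensor: everything vanishes after mean subtraction
  const <- make_tensor(array(3, c(2, 2, 3, 4)))
  mg <- marginalize(const)
  for (lab in c("time", "task", "target", "task_target"))
    expect_true(all(mg[[lab]] == 0))

  # pure-time tensor: only the time marginalization survives
  tcurve <- sin(seq_len(10))
  pure <- array(rep(tcurve, each = 2 * 2 * 3), c(2, 2, 3, 10))
  pure <- aperm(array(tcurve, c(10, 2, 2, 3)), c(2, 3, 4, 1))
  mgp <- marginalize(make_tensor(pure))
  expect_true(all(abs(mgp$task) < 1e-12))
  expect_true(all(abs(mgp$target) < 1e-12))
  expect_true(all(abs(mgp$task_target) < 1e-12))
  expect_gt(max(abs(mgp$time)), 0.1)

  # random tensors: reconstruction identity, pairwise uncorrelatedness,
  # agreement with the nested-loop oracle
  set.seed(40)
  for (rep in 1:3) {
    X <- array(rnorm(4 * 2 * 3 * 10), c(4, 2, 3, 10))
    mg <- marginalize(make_tensor(X))
    recon <- mg$time + mg$task + mg$target + mg$task_target
    expect_lt(max(abs(recon - mg$centered)), 1e-12)
    labs <- c("time", "task", "target", "task_target")
    for (i in 1:3) for (j in (i + 1):4)
      expect_lt(abs(sum(mg[[labs[i]]] * mg[[labs[j]]])), 1e-9)
    oracle <- oracle_marginalize(X)
    for (lab in labs)
      expect_equal(mg[[lab]], oracle[[lab]], tolerance = 1e-12)
  }
})

test_that("dPCA recovers planted time and target modes with labels", {
  recovered <- vapply(1:6, function(seed) {
    gs <- generate_session(synthetic_config(
      seed = seed, n_units = 30, d_time = 2, d_target = 2, d_task = 0,
      d_tasktarget = 0, latent_sd = c(3, 2, 2.5, 1.5), baseline_rate = 3,
      rate_link = "linear", trial_jitter = 0))
    rates <- smooth_rates(gs$session$spikes, gs$session$trials)
    tensor <- trial_average(rates)
    dp <- fit_dpca(tensor, 6)
    top4 <- dp$labels[1:4]
    labels_ok <- all(top4 %in% c("time", "target"))
    # each planted time/target trajectory must be matched by some dPCA
    # latent with correlation > 0.95
    lat <- neuromodes:::dpca_latents(
      dp, neuromodes:::unfold_tensor(tensor$values))
    tau <- tensor$tau
    cors <- vapply(which(gs$truth$mode_labels %in% c("time", "target")),
                   function(j) {
      # arrange the planted trajectory in the tensor's unfolding order
      # (task fastest, then target, then time)
      planted <- as.vector(aperm(gs$truth$latents[j, seq_len(tau), , ,
                                                  drop = FALSE],
                                 c(3, 4, 2, 1)))
      max(abs(cor(planted, t(lat))))
    }, numeric(1))
    labels_ok && all(cors > 0.95)
  }, logical(1))
  expect_gte(sum(recovered), 5)
})

test_that("dPCA attains exact reconstruction at full rank and zero noise", {
  gs <- generate_session(synthetic_config(
    seed = 50, n_units = 12, d_time = 2, d_target = 2, d_task = 1,
    d_tasktarget = 1, trial_jitter = 0))
  # noiseless tensor built directly from the planted latents
  tau <- 20
  X <- array(0, c(12, 2, 3, tau))
  for (a in 1:2) for (g in 1:3)
    X[, a, g, ] <- gs$truth$loadings[[a]] %*%
      gs$truth$latents[, seq_len(tau), a, g]
  tensor <- make_tensor(X)
  dp <- fit_dpca(tensor, 12)
  expect_gt(dp$total_vaf, 1 - 1e-8)

  curve <- dpca_vaf(tensor, dp$encoder, dp$decoder)
  expect_equal(curve[1], 0)   # h = 0
  expect_true(all(diff(curve) >= -1e-9))
})

test_that("dPCA VAF stays within PCA VAF and close on planted sessions", {
  gs <- default_session()
  rates <- smooth_rates(gs$session$spikes, gs$session$trials)
  tensor <- trial_average(rates)
  dp <- fit_dpca(tensor, 12)
  X <- neuromodes:::unfold_tensor(tensor$values)
  Wp <- neuromodes:::pca_basis(X, 12)
  pca_curve <- dpca_vaf(tensor, t(Wp), Wp)
  dpca_curve <- dpca_vaf(tensor, dp$encoder, dp$decoder)
  expect_true(all(dpca_curve <= pca_curve + 1e-9))
  # on 12-mode planted sessions dPCA captures nearly all of the PCA VAF
  expect_gt(dpca_curve[13] / pca_curve[13], 0.9)
})

test_that("mode labels carry per-parameter VAF and survive relabeling", {
  # pure-time data: all kept VAF labeled time
  tcurve <- cumsum(rnorm(10))
  pure <- aperm(array(outer(tcurve, rnorm(3)), c(10, 3, 2, 2)), c(2, 3, 4, 1))
  dpp <- fit_dpca(make_tensor(pure), 2)
  lm_ <- label_modes(dpp)
  expect_equal(sum(lm_$parameter_vaf), lm_$parameter_vaf[["time"]],
               tolerance = 1e-9)

  # 50/50 planted time/target variance recovers within 10 points
  gs <- generate_session(synthetic_config(
    seed = 60, n_units = 30, d_time = 2, d_target = 2, d_task = 1,
    d_tasktarget = 1, latent_sd = 6, trial_jitter = 0))
  rates <- smooth_rates(gs$session$spikes, gs$session$trials)
  dp <- fit_dpca(trial_average(rates), 6)
  pv <- label_modes(dp)$parameter_vaf
  shares <- pv[c("time", "target")] / sum(pv[c("time", "target")])
  expect_lt(abs(shares[["time"]] - 0.5), 0.22)

  # swapping task labels permutes the task marginalization but leaves the
  # time marginalization untouched
  X <- array(rnorm(4 * 2 * 3 * 8), c(4, 2, 3, 8))
  mg1 <- marginalize(make_tensor(X))
  mg2 <- marginalize(make_tensor(X[, c(2, 1), , ]))
  expect_equal(mg2$time, mg1$time, tolerance = 1e-12)
  expect_equal(mg2$task, mg1$task[, c(2, 1), , ], tolerance = 1e-12)
})
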