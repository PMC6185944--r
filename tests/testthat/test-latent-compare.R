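test_that("match_and_concat equalizes trials and windows", {
  gs <- default_session()
  s <- gs$session
  mm <- suppressWarnings(match_and_concat(s, 1, 1, window_ms = 600))
  expect_equal(mm$L_a, mm$L_b)
  w <- mm$window_bins
  expect_equal(w, 30)   # 600 ms at 20 ms bins
  expect_equal(ncol(mm$L_a), w * mm$k * length(mm$targets))

  # 700 ms default window = 35 bins when trials are long enough
  long <- generate_session(synthetic_config(seed = 8, trial_jitter = 0,
                                            trial_len = 40,
                                            n_trials_per_condition = 4))
  mm7 <- match_and_concat(long$session, 1, 2)
  expect_equal(mm7$window_bins, 35)
})

test_that("2-D targets map to 1-D labels by horizontal projection", {
  angles <- c(0, 60, 120, 180, 240, 300)
  # hand-built lookup: cos > 0 -> 1, cos < 0 -> 2
  expect_equal(horizontal_target_map(angles), c(1L, 1L, 2L, 2L, 2L, 1L))
  expect_true(is.na(horizontal_target_map(90)))
})

test_that("cca reproduces identities and affine invariance", {
  set.seed(20)
  L <- matrix(rnorm(3 * 80), 3)
  r <- cca(L, L)
  expect_true(all(abs(r$correlations - 1) < 1e-10))
  Theta <- matrix(rnorm(9), 3) + diag(3)
  r2 <- cca(L, Theta %*% L)
  expect_true(all(abs(r2$correlations - 1) < 1e-9))
  # symmetry of the correlation spectrum
  M <- matrix(rnorm(3 * 80), 3)
  expect_equal(cca(L, M)$correlations, cca(M, L)$correlations,
               tolerance = 1e-9)
  # stored correlations match correlations of the aligned variates
  rr <- cca(L, M)
  for (i in 1:3)
    expect_equal(abs(cor(rr$aligned_a[i, ], rr$aligned_b[i, ])),
                 rr$correlations[i], tolerance = 1e-8)
  # rank-deficient input is refused with the side named
  Ldef <- rbind(L[1, ], L[1, ], L[2, ])
  expect_error(cca(Ldef, M), "rank error.*A")
})

test_that("leading canonical correlation matches brute-force maximization", {
  set.seed(21)
  shared <- rnorm(200)
  L_a <- rbind(shared + 0.05 * rnorm(200), rnorm(200))
  L_b <- rbind(rnorm(200), shared + 0.05 * rnorm(200))
  r <- cca(L_a, L_b)
  expect_gt(r$correlations[1], 0.95)
  expect_lt(r$correlations[2], 0.4)
  expect_equal(r$correlations[1], oracle_leading_cc(L_a, L_b),
               tolerance = 1e-4)
})

test_that("noiseless sessions give within-task ceilings of one", {
  s <- deterministic_session()
  set.seed(22)
  ceil <- suppressWarnings(within_task_ceiling(s, 1, n_reps = 10,
                                               window_ms = 400, m = 4))
  expect_true(all(abs(ceil$ceiling - 1) < 1e-6))
})

test_that("ceilings degrade as Poisson noise grows", {
  mean_ceiling <- vapply(c(6, 3, 1.5), function(amp) {
    gs <- generate_session(synthetic_config(seed = 30, latent_sd = amp,
                                            n_units = 40))
    set.seed(31)
    ceil <- within_task_ceiling(gs$session, 1, n_reps = 15, m = 8)
    mean(ceil$ceiling)
  }, numeric(1))
  expect_true(all(diff(mean_ceiling) < 0))
})

test_that("bootstrap null separates real correspondence from chance", {
  gs <- default_session()
  mm <- suppressWarnings(match_and_concat(gs$session, 1, 2,
                                          window_ms = 600))
  set.seed(23)
  nullr <- bootstrap_null(mm$L_a, mm$L_b, n_boot = 1000)
  # a latent set against itself: all CCs are 1, above any null threshold
  self_cc <- cca(mm$L_a, mm$L_a)$correlations
  expect_true(all(self_cc > nullr$threshold))
  expect_error(bootstrap_null(mm$L_a, mm$L_b, n_boot = 100), "resolution")

  # independent white-noise latents: leading CC below the null threshold
  set.seed(24)
  hits <- vapply(1:10, function(r) {
    A <- matrix(rnorm(12 * 2000), 12)
    B <- matrix(rnorm(12 * 2000), 12)
    obs <- cca(A, B)$correlations[1]
    thr <- bootstrap_null(A, B, n_boot = 500, probs = 0.99)$threshold[1]
    obs < thr
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("CCA-direction VAF never exceeds PCA VAF and matches at h = m", {
  gs <- small_session()
  rates <- smooth_rates(gs$session$spikes, gs$session$trials)
  ra <- neuromodes:::task_rates(rates, 1)
  rb <- neuromodes:::task_rates(rates, 2)
  m <- 6
  mm <- suppressWarnings(match_and_concat(gs$session, 1, 2, m = m,
                                          window_ms = 400))
  cc <- cca(mm$L_a, mm$L_b)
  # VAF computed on the matched windows the latents came from
  Xa <- mm$manifold_a$W %*% mm$L_a + mm$manifold_a$mean
  va_cca <- cca_vaf(Xa, mm$manifold_a, cc$M_a)
  pca_m <- fit_pca(Xa, m)
  va_pca <- vapply(1:m, function(h)
    vaf(Xa - rowMeans(Xa), t(pca_m$W[, 1:h, drop = FALSE]),
        pca_m$W[, 1:h, drop = FALSE]), numeric(1))
  expect_true(all(va_cca <= va_pca + 1e-9))
  expect_equal(va_cca[m], va_pca[m], tolerance = 1e-9)
})
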