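test_that("fit_pca recovers embedded covariance structure exactly", {
  # rank-2 data: trailing eigenvalues vanish
  set.seed(3)
  W2 <- neuromodes:::random_orthonormal(6, 2)
  X <- W2 %*% matrix(rnorm(2 * 100), 2)
  suppressWarnings(mani <- fit_pca(X, 2))
  expect_lt(max(abs(fit_pca(X, 6)$eigenvalues[3:6])), 1e-9)

  # 3-unit toy with a known 2x2 covariance embedded: modes match the
  # analytic eigenvectors of the 3x3 covariance
  C2 <- matrix(c(4, 1.2, 1.2, 1), 2)
  Q <- neuromodes:::random_orthonormal(3, 2)
  X3 <- rates_with_covariance(C2, Q, T_len = 60)
  mani3 <- fit_pca(X3, 2)
  C3 <- Q %*% C2 %*% t(Q)
  eC <- eigen(C3, symmetric = TRUE)
  expect_equal(mani3$eigenvalues[1:2], eC$values[1:2], tolerance = 1e-8)
  for (j in 1:2)
    expect_lt(min(sum((mani3$W[, j] - eC$vectors[, j])^2),
                  sum((mani3$W[, j] + eC$vectors[, j])^2)), 1e-8)

  expect_error(fit_pca(X3, 5), "exceeds")
  expect_error(fit_pca(matrix(1, 3, 50), 2), "degenerate")
})

test_that("projection yields latents with eigenvalue variances", {
  set.seed(4)
  X <- matrix(rnorm(5 * 100), 5)
  mani <- fit_pca(X, 2)
  lat <- project(X, mani)
  expect_equal(apply(lat$values, 1, var), mani$eigenvalues[1:2],
               tolerance = 1e-8)
  # constant data at the mean projects to zero
  Xm <- matrix(mani$mean, 5, 10)
  expect_lt(max(abs(project(Xm, mani)$values)), 1e-10)
  # data inside the manifold reconstructs exactly
  Z <- mani$W %*% matrix(rnorm(2 * 50), 2)
  latZ <- project(Z + rowMeans(Z) * 0, fit_pca(Z, 2))
  m2 <- fit_pca(Z, 2)
  rec <- m2$W %*% project(Z, m2)$values + m2$mean
  expect_lt(max(abs(rec - Z)), 1e-9)
  expect_error(project(matrix(0, 4, 10), mani), "unit count")
})

test_that("vaf matches the eigenvalue ratio for PCA encoders", {
  set.seed(5)
  X <- matrix(rnorm(4 * 50), 4)
  Xc <- X - rowMeans(X)
  expect_equal(vaf(Xc, diag(4), diag(4)), 1)
  mani <- fit_pca(X, 2)
  ev <- mani$eigenvalues
  expect_equal(vaf(Xc, t(mani$W), mani$W), (ev[1] + ev[2]) / sum(ev),
               tolerance = 1e-9)
  # direction orthogonal to all data
  W2 <- neuromodes:::random_orthonormal(6, 2)
  Y <- W2 %*% matrix(rnorm(2 * 80), 2)
  Yc <- Y - rowMeans(Y)
  orth <- qr.Q(qr(cbind(W2, rnorm(6))))[, 3, drop = FALSE]
  expect_lt(abs(vaf(Yc, t(orth), orth)), 1e-10)
  expect_error(vaf(X + 10, diag(4), diag(4)), "mean-subtracted")
})

test_that("vaf is invariant to unit reordering and nondecreasing in h", {
  set.seed(6)
  X <- matrix(rnorm(8 * 120), 8)
  Xc <- X - rowMeans(X)
  mani <- fit_pca(X, 8)
  perm <- sample(8)
  v1 <- vaf(Xc, t(mani$W[, 1:3]), mani$W[, 1:3])
  v2 <- vaf(Xc[perm, ], t(mani$W[perm, 1:3]), mani$W[perm, 1:3])
  expect_equal(v1, v2, tolerance = 1e-12)
  curve <- vapply(1:8, function(h)
    vaf(Xc, t(mani$W[, 1:h, drop = FALSE]),
        mani$W[, 1:h, drop = FALSE]), numeric(1))
  expect_true(all(diff(curve) >= -1e-12))
})

test_that("across-task VAF ratio behaves at its extremes and on shared data", {
  gs <- default_session()
  rates <- smooth_rates(gs$session$spikes, gs$session$trials)
  ra <- neuromodes:::task_rates(rates, 1)
  ma <- fit_pca(ra, 12)
  expect_equal(across_task_vaf_ratio(ra, ma, ma), 1)

  # manifold orthogonal to the data subspace gives ratio 0
  set.seed(7)
  W2 <- neuromodes:::random_orthonormal(10, 2)
  X <- W2 %*% matrix(rnorm(2 * 200), 2)
  full <- qr.Q(qr(cbind(W2, matrix(rnorm(10 * 2), 10))))
  orth_mani <- structure(list(W = full[, 3:4], mean = rep(0, 10),
                              eigenvalues = rep(1, 10), m = 2),
                         class = "manifold")
  suppressWarnings(own <- fit_pca(X, 2))
  expect_lt(across_task_vaf_ratio(X, own, orth_mani), 1e-10)

  # shared-subspace synthetic tasks: ratio matches the explicit
  # reconstruction-loop oracle
  mb <- fit_pca(neuromodes:::task_rates(rates, 2), 12)
  Xc <- ra$values - rowMeans(ra$values)
  rec_vaf <- function(W) {
    R <- W %*% crossprod(W, Xc)
    (sum(Xc^2) - sum((Xc - R)^2)) / sum(Xc^2)
  }
  expect_equal(across_task_vaf_ratio(ra, ma, mb),
               rec_vaf(mb$W) / rec_vaf(ma$W), tolerance = 1e-12)
})

test_that("random-manifold control concentrates at m/n for isotropic data", {
  set.seed(8)
  X <- matrix(rnorm(20 * 400), 20)
  set.seed(9)
  ctrl <- random_manifold_control(X, m = 2, n_draws = 200)
  # independent larger Monte-Carlo oracle
  Xc <- X - rowMeans(X)
  tot <- sum(Xc^2)
  set.seed(10)
  oracle <- replicate(2000, {
    G <- matrix(rnorm(20 * 2), 20)
    Q <- qr.Q(qr(G))
    sum(crossprod(Q, Xc)^2) / tot
  })
  se <- sd(oracle) / sqrt(length(ctrl$vafs))
  expect_lt(abs(mean(ctrl$vafs) - mean(oracle)), 3 * se + 0.003)
  expect_equal(mean(ctrl$vafs), 2 / 20, tolerance = 0.05)

  # m = n: every random basis spans the whole space
  set.seed(11)
  Y <- matrix(rnorm(5 * 100), 5)
  ctrl_full <- random_manifold_control(Y, m = 5, n_draws = 100)
  expect_true(all(abs(ctrl_full$vafs - 1) < 1e-9))
  expect_error(random_manifold_control(Y, 2, n_draws = 10), ">= 100")
})
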