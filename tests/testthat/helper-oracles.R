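# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Principal angles by deflation + alternating power iteration on the
# inner-product matrix (no SVD call).
oracle_principal_angles <- function(W_a, W_b, iters = 2000) {
  M <- crossprod(W_a, W_b)
  m <- ncol(M)
  angles <- numeric(m)
  M_work <- M
  for (r in seq_len(m)) {
    q <- rnorm(m); q <- q / sqrt(sum(q^2))
    p <- numeric(m)
    for (it in seq_len(iters)) {
      p_new <- M_work %*% q
      np <- sqrt(sum(p_new^2))
      if (np < 1e-300) { p_new <- rnorm(m); np <- sqrt(sum(p_new^2)) }
      p <- p_new / np
      q_new <- crossprod(M_work, p)
      nq <- sqrt(sum(q_new^2))
      if (nq < 1e-300) { q_new <- rnorm(m); nq <- sqrt(sum(q_new^2)) }
      q <- q_new / nq
    }
    cosang <- as.numeric(crossprod(p, M %*% q))
    angles[r] <- acos(min(max(abs(cosang), 0), 1)) * 180 / pi
    M_work <- (diag(m) - tcrossprod(p)) %*% M_work %*%
      (diag(m) - tcrossprod(q))
  }
  sort(angles)
}

# Leading canonical correlation for m = 2 by dense grid over the two weight
# angles + Nelder-Mead refinement of the Pearson correlation.
oracle_leading_cc <- function(L_a, L_b, grid_n = 180) {
  Ac <- L_a - rowMeans(L_a)
  Bc <- L_b - rowMeans(L_b)
  corr_of <- function(th) {
    wa <- c(cos(th[1]), sin(th[1]))
    wb <- c(cos(th[2]), sin(th[2]))
    abs(stats::cor(as.numeric(wa %*% Ac), as.numeric(wb %*% Bc)))
  }
  grid <- seq(0, pi, length.out = grid_n + 1)[-(grid_n + 1)]
  best <- c(0, 0); best_val <- -1
  for (ta in grid) for (tb in grid) {
    v <- corr_of(c(ta, tb))
    if (is.finite(v) && v > best_val) { best_val <- v; best <- c(ta, tb) }
  }
  opt <- stats::optim(best, function(th) -corr_of(th),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  -opt$value
}

# Explicit loop convolution of one row with a unit-mass Gaussian kernel,
# zero-padded edges.
oracle_convolve <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_along(kernel)) {
      src <- t + j - half - 1
      if (src >= 1 && src <= n) acc <- acc + kernel[j] * x[src]
    }
    out[t] <- acc
  }
  out
}

# Explicit nested-loop factorial marginalization of an n x a x g x t array.
oracle_marginalize <- function(X) {
  dn <- dim(X)
  grand <- apply(X, 1, mean)
  Xc <- X
  for (i in seq_len(dn[1])) Xc[i, , , ] <- X[i, , , ] - grand[i]
  timem <- array(0, dn); taskm <- array(0, dn)
  targm <- array(0, dn); ttm <- array(0, dn)
  for (i in seq_len(dn[1])) for (t in seq_len(dn[4])) {
    tmean <- mean(Xc[i, , , t])
    for (a in seq_len(dn[2])) for (g in seq_len(dn[3])) {
      amean <- mean(Xc[i, a, , t])
      gmean <- mean(Xc[i, , g, t])
      timem[i, a, g, t] <- tmean
      taskm[i, a, g, t] <- amean - tmean
      targm[i, a, g, t] <- gmean - tmean
      ttm[i, a, g, t] <- Xc[i, a, g, t] - amean - gmean + tmean
    }
  }
  list(time = timem, task = taskm, target = targm, task_target = ttm,
       centered = Xc)
}
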