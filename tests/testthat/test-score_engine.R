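test_that("intercept-only precompute is the scalar closed form", {
  rf <- random_fit(n = 100, q = 1, seed = 7, family = "poisson")
  pc <- precompute_score(rf$fit, rf$Z)
  expect_equal(as.numeric(pc$S), 1 / sqrt(sum(pc$w)), tolerance = 1e-10)
  expect_equal(pc$a, pc$w * rf$fit$working_resid, tolerance = 1e-12)
})

test_that("S satisfies ||S v||^2 = v' (Z'WZ)^{-1} v", {
  rf <- random_fit(n = 300, q = 8, seed = 12)
  pc <- precompute_score(rf$fit, rf$Z)
  ZtWZ <- crossprod(rf$Z, rf$Z * rf$fit$w)
  set.seed(1)
  for (k in 1:5) {
    v <- rnorm(8)
    expect_equal(sum((pc$S %*% v)^2),
                 as.numeric(crossprod(v, solve(ZtWZ, v))),
                 tolerance = 1e-8)
  }
})

test_that("intercept-only Poisson score statistic has the closed form", {
  # with mu_hat = Ybar and w = Ybar: z = sum_T (Y - Ybar) /
  # sqrt(Ybar * t * (1 - t/n))
  set.seed(21)
  Y <- rpois(80, 4)
  fit <- fit_null_glm(Y, matrix(1, 80, 1), family = "poisson",
                      tol = 1e-14)
  pc <- precompute_score(fit, matrix(1, 80, 1))
  idx <- sort(sample(80, 13))
  ybar <- mean(Y)
  z_closed <- sum(Y[idx] - ybar) / sqrt(ybar * 13 * (1 - 13 / 80))
  expect_equal(score_stat(idx, pc), z_closed, tolerance = 1e-8)
  x <- as.numeric(seq_len(80) %in% idx)
  expect_equal(score_stat_qr(x, fit, matrix(1, 80, 1)), z_closed,
               tolerance = 1e-8)
})

test_that("spectral = dense = QR on many random instances", {
  n_inst <- 0
  for (seed in 1:25) {
    rf <- random_fit(n = 120, q = sample(2:6, 1), seed = seed)
    pc <- precompute_score(rf$fit, rf$Z)
    set.seed(seed + 1000)
    for (k in 1:20) {
      t_ <- sample(2:60, 1)
      idx <- sort(sample(120, t_))
      x <- as.numeric(seq_len(120) %in% idx)
      z_sp <- score_stat(idx, pc)
      z_de <- score_stat_dense(x, rf$fit, rf$Z)
      z_qr <- score_stat_qr(x, rf$fit, rf$Z)
      expect_equal(z_sp, z_de, tolerance = 1e-8)
      expect_equal(z_sp, z_qr, tolerance = 1e-8)
      n_inst <- n_inst + 1
    }
  }
  expect_gte(n_inst, 500)
})

test_that("score statistic agrees with the statmod reference", {
  set.seed(30)
  n <- 500
  z2 <- rnorm(n)
  Y <- rnbinom(n, size = 6, mu = exp(0.8 + 0.4 * z2))
  x <- rbinom(n, 1, 0.1)
  # same fixed-theta fit on both sides so the statistics are comparable
  mfit <- suppressWarnings(MASS::glm.nb(Y ~ z2))
  fit <- fit_null_glm(Y, cbind(1, z2), family = mfit$theta)
  pc <- precompute_score(fit, cbind(1, z2))
  # dispersion = 1: the NB variance is carried by theta, not a
  # quasi-likelihood dispersion factor
  expect_equal(score_stat(which(x == 1), pc),
               as.numeric(statmod::glm.scoretest(mfit, x, dispersion = 1)),
               tolerance = 1e-4)
})

test_that("perfect fit gives z = 0 and degenerate sets error", {
  rf <- random_fit(n = 60, q = 2, seed = 2)
  fit <- rf$fit
  fit$working_resid <- rep(0, 60)
  pc <- precompute_score(fit, rf$Z)
  expect_equal(score_stat(c(3L, 9L, 30L), pc), 0)
  expect_error(score_stat(integer(0), pc), "degenerate")
  expect_error(score_stat(1:60, pc), "degenerate")
})

test_that("z is invariant under joint reordering of cells", {
  rf <- random_fit(n = 90, q = 3, seed = 8)
  set.seed(5)
  perm <- sample(90)
  idx <- sort(sample(90, 20))
  x <- as.numeric(seq_len(90) %in% idx)
  z1 <- score_stat_qr(x, rf$fit, rf$Z)
  fitp <- fit_null_glm(rf$Y[perm], rf$Z[perm, ], family = "nb")
  z2 <- score_stat_qr(x[perm], fitp, rf$Z[perm, ])
  expect_equal(z1, z2, tolerance = 1e-6)
})

test_that("null z's are approximately standard normal at large n", {
  # simulate from a fitted null model, assign treatment independently
  set.seed(77)
  n <- 800
  Z <- cbind(1, rnorm(n))
  mu <- exp(1.0 + 0.3 * Z[, 2])
  zs <- numeric(2000)
  Y <- rnbinom(n, size = 5, mu = mu)
  fit <- fit_null_glm(Y, Z, family = "nb")
  pc <- precompute_score(fit, Z)
  for (b in seq_len(2000)) {
    idx <- sample(n, 80)
    zs[b] <- score_stat(sort(idx), pc)
  }
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(var(zs) - 1), 0.1)
})

test_that("batch kernel matches per-set evaluation", {
  rf <- random_fit(n = 150, q = 4, seed = 17)
  pc <- precompute_score(rf$fit, rf$Z)
  bank <- resample_bank(150, seed = 3, "kernel_test")
  o <- screenperm:::bank_orderings(bank, 50)
  zb <- screenperm:::score_stats_permuted(pc, o, 12)
  z_ref <- vapply(1:50, function(b)
    score_stat(sort(o[1:12, b]), pc), 0.0)
  expect_equal(zb, z_ref, tolerance = 1e-12)
})
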