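test_that("PLSC saliences reduce to the correlation profile", {
  # few enough noise features that the norm statistic has power at n = 8
  withr::with_seed(3, {
    n <- 8
    X <- matrix(rnorm(n * 8), n)
    y <- X[, 3] + rnorm(n, 0, 1e-8)
  })
  fit <- plsc(X, y, n_perm = 200, n_boot = 300, seed = 42)
  expect_equal(which.max(abs(fit$saliences)), 3L, ignore_attr = TRUE)
  expect_equal(which.max(abs(fit$bootstrap_ratios)), 3L, ignore_attr = TRUE)
  expect_equal(fit$singular_value, sqrt(sum(cor(y, X)^2)), tolerance = 1e-12)
  expect_equal(sum(fit$saliences^2), 1, tolerance = 1e-12)
  # the norm statistic pools chance correlations from the noise
  # features, so at n = 8 the perfect column lowers p only moderately
  expect_lt(fit$p_perm, 0.2)
  # fixed seed: bit-identical resampling results
  fit2 <- plsc(X, y, n_perm = 200, n_boot = 300, seed = 42)
  expect_identical(fit, fit2)
  expect_error(plsc(X[1:3, ], y[1:3]), "at least 4")
  expect_error(plsc(X, rep(1, n)), "zero variance")
  Xz <- X; Xz[, 5] <- 2
  expect_warning(fz <- plsc(Xz, y, n_perm = 0, n_boot = 0), "zero-variance")
  expect_length(fz$saliences, 7L)
})

test_that("permutation p-values are valid under the null", {
  withr::with_seed(77, {
    p_vals <- replicate(150, {
      y <- rnorm(8)
      X <- matrix(rnorm(8 * 30), 8)
      plsc(X, y, n_perm = 99, n_boot = 0)$p_perm
    })
  })
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(p_vals <= a), a + 2 * sqrt(a * (1 - a) / 150))
  expect_true(all(p_vals > 0 & p_vals <= 1))
})

test_that("PLSR solves noiseless linear problems exactly", {
  withr::with_seed(5, {
    X <- matrix(rnorm(8 * 4), 8)
    y <- as.vector(X %*% c(1, -2, 0.5, 0)) + 3
  })
  fit <- plsr_fit(X, y, n_latent = 4)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # k = 2 latent variables already suffice near-perfectly here is not
  # guaranteed; full deflation is
  expect_error(suppressWarnings(plsr_fit(X, y, n_latent = 9)), "rank")
})

test_that("single-feature PLSR equals the least-squares slope", {
  withr::with_seed(6, {
    X <- matrix(rnorm(10), 10)
    y <- 2 * X[, 1] + rnorm(10, 0, 0.1)
  })
  fit <- plsr_fit(X, y, n_latent = 1)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("full-rank PLSR reproduces OLS predictions", {
  withr::with_seed(7, {
    for (i in 1:5) {
      X <- matrix(rnorm(12 * 3), 12)
      y <- rnorm(12)
      fit <- plsr_fit(X, y, n_latent = 3)
      expect_equal(fit$fitted, unname(fitted(lm(y ~ X))), tolerance = 1e-6)
    }
  })
})

test_that("PLSR predictions match an independent PLS1 reference", {
  withr::with_seed(19, {
    for (i in 1:20) {
      n <- sample(6:15, 1)
      p <- sample(2:12, 1)
      k <- sample(seq_len(min(p, n - 2)), 1)
      X <- matrix(rnorm(n * p), n)
      y <- rnorm(n)
      Xnew <- matrix(rnorm(4 * p), 4)
      fit <- plsr_fit(X, y, n_latent = k)
      expect_equal(predict(fit, Xnew), ref_pls1_predict(X, y, k, Xnew),
                   tolerance = 1e-6)
    }
  })
})

test_that("mean-only fallback handles constant responses", {
  X <- matrix(rnorm(8 * 3), 8)
  fit <- plsr_fit(X, rep(4, 8))
  expect_equal(fit$n_latent, 0L)
  expect_equal(predict(fit, X), rep(4, 8))
  ev <- loo_evaluate(X, rep(4, 8))
  expect_equal(ev$rmse, 0)
})

test_that("LOO recovery is near-exact for noiseless planted models", {
  withr::with_seed(13, {
    X <- matrix(rnorm(8 * 3), 8)
    y <- as.vector(X %*% c(2, 1, -1)) + 10
  })
  ev <- loo_evaluate(X, y, n_latent = 3)
  expect_lt(ev$rmse_pct, 1)
  expect_equal(ev$slope, 1, tolerance = 0.02)
  # rmse_pct invariant under positive rescaling of y
  ev2 <- loo_evaluate(X, 3.7 * y, n_latent = 3)
  expect_equal(ev2$rmse_pct, ev$rmse_pct, tolerance = 1e-9)
  expect_error(loo_evaluate(X[1:2, ], y[1:2]), "at least 3")
})

test_that("regression power follows the noncentral-F contract", {
  # study-scale configuration: R2 0.855 with 2 predictors over 7
  # sessions clears the 0.8 power requirement at alpha 0.05
  expect_gt(regression_power(0.855, 7, 2), 0.8)
  expect_equal(regression_power(0.855, 7, 2), 0.9630397, tolerance = 1e-6)
  expect_equal(regression_power(1e-14, 9, 3), 0.05, tolerance = 1e-6)
  expect_error(regression_power(0.5, 4, 3), "n > k")
  expect_error(regression_power(1.2, 9, 3))
  expect_error(regression_power(-0.1, 9, 3))
  # monotone in R2 and in n
  expect_gt(regression_power(0.7, 10, 3), regression_power(0.5, 10, 3))
  expect_gt(regression_power(0.5, 16, 3), regression_power(0.5, 10, 3))
})

test_that("pruning stops at the power target and drops one channel a step", {
  d <- planted_design(n = 10, p = 5, snr = 8, seed = 3)
  pr <- suppressWarnings(prune_channels(d$X, d$y, n_latent = 1))
  expect_true(all(diff(pr$history$k) == -1))
  expect_true(pr$power_met)
  expect_gte(pr$power, 0.8)
  # signal channels survive pruning
  expect_true(all(pr$channels %in% colnames(d$X)))
  expect_true(any(d$planted %in% pr$channels))
  # already-satisfied power: zero removals
  withr::with_seed(4, {
    X <- matrix(rnorm(12 * 2), 12)
    y <- as.vector(X %*% c(1, 1)) + rnorm(12, 0, 0.1)
  })
  pr2 <- prune_channels(X, y)
  expect_equal(nrow(pr2$history), 1L)
  expect_equal(length(pr2$channels), 2L)
})

test_that("pruning retains the signal-carrying channels", {
  hits <- 0
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      n <- 10
      y <- rnorm(n)
      X <- cbind(y + rnorm(n, 0, 0.15), y + rnorm(n, 0, 0.15),
                 matrix(rnorm(n * 3), n))
      colnames(X) <- paste0("c", 1:5)
    })
    pr <- suppressWarnings(
      prune_channels(X, y, target_power = 0.999, n_latent = 1))
    if (all(c("c1", "c2") %in% pr$channels) ||
        setequal(pr$channels, c("c1", "c2")) ||
        all(pr$channels %in% c("c1", "c2")))
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("consensus selection recalls planted channels at study scale", {
  hits <- 0
  for (s in 1:5) {
    d <- planted_design(n = 8, p = 200, snr = 5, seed = 200 + s)
    cc <- suppressMessages(
      consensus_channels(d$X, d$y, n_reps = 15, n_boot = 150,
                         seed = 17 * s))
    if (all(d$planted %in% cc$channels)) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("consensus separates planted from noise in the consistency regime", {
  exact <- 0; empty <- 0
  for (s in 1:5) {
    d <- planted_design(n = 40, p = 150, snr = 5, seed = 300 + s,
                        y = withr::with_seed(300 + s, rnorm(40)))
    cc <- suppressMessages(
      consensus_channels(d$X, d$y, n_reps = 12, bsr_threshold = 8,
                         n_boot = 150, seed = 23 * s))
    if (setequal(cc$channels, d$planted)) exact <- exact + 1
    X0 <- withr::with_seed(400 + s, matrix(rnorm(40 * 150), 40))
    colnames(X0) <- paste0("f", 1:150)
    c0 <- suppressMessages(
      consensus_channels(X0, withr::with_seed(500 + s, rnorm(40)),
                         n_reps = 12, bsr_threshold = 8, n_boot = 150,
                         seed = 29 * s))
    if (length(c0$channels) == 0) empty <- empty + 1
  }
  expect_gte(exact, 4)
  expect_gte(empty, 4)
})

test_that("consensus fraction boundary frac = 0 keeps any selected feature", {
  d <- planted_design(n = 8, p = 30, snr = 5, seed = 9)
  cc0 <- suppressMessages(
    consensus_channels(d$X, d$y, n_reps = 8, frac = 0, n_boot = 100,
                       seed = 5))
  cc8 <- suppressMessages(
    consensus_channels(d$X, d$y, n_reps = 8, frac = 0.8, n_boot = 100,
                       seed = 5))
  expect_true(all(cc8$channels %in% cc0$channels))
  expect_setequal(cc0$channels, names(cc0$fraction)[cc0$fraction > 0])
})
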