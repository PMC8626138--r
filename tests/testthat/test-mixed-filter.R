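true_params <- mixed_params(rho = 0.95, alpha = 10, beta = 2,
                            var_eta = 0.05, var_eps = 0.5,
                            mu = qlogis(0.05))

test_that("chance probability maps to the Bernoulli offset by the logit", {
  expect_equal(mu_from_chance(0.5), 0)
  expect_equal(mu_from_chance(0.1), -2.19722, tolerance = 1e-5)
  expect_error(mu_from_chance(0), "strictly inside")
  expect_error(mu_from_chance(1), "strictly inside")
  # round trip with the observation model
  expect_equal(logistic_prob(mu_from_chance(0.1), 0), 0.1)
})

test_that("logistic transform is overflow-safe and strictly inside (0, 1)", {
  expect_equal(logistic_prob(0, 0), 0.5)
  expect_equal(logistic_prob(-2.19722, 0), 0.1, tolerance = 1e-5)
  expect_lt(abs(logistic_prob(0, 50) - 1), 1e-15)
  p <- logistic_prob(0, c(-800, 800))
  expect_true(all(p > 0 & p < 1))
})

test_that("mixed simulation has the stated dynamics and is seed-reproducible", {
  # degenerate dynamics: no process noise, forced x0 = 0
  quiet <- mixed_params(0.9, 5, 1, 1e-30, 0.25, qlogis(0.2))
  s <- simulate_mixed(quiet, 4000, seed = 2, x0 = 0)
  expect_lt(max(abs(s$x)), 1e-10)
  expect_equal(mean(s$v), 5, tolerance = 0.05)
  expect_equal(mean(s$lambda), 0.2, tolerance = 0.03)

  # AR(1) lag-one autocorrelation
  ar <- mixed_params(0.98, 0, 1, 0.1, 1, 0)
  s2 <- simulate_mixed(ar, 50000, seed = 3)
  r1 <- cor(s2$x[-1], s2$x[-50000])
  expect_lt(abs(r1 - 0.98), 0.01)

  expect_identical(simulate_mixed(true_params, 100, seed = 9),
                   simulate_mixed(true_params, 100, seed = 9))
})

test_that("forward filter reduces to the continuous channel when it dominates", {
  p <- mixed_params(0.9, 1, 5, 0.1, 1e-8, 0)
  s <- simulate_mixed(p, 50, seed = 4)
  tr <- forward_filter(s$v, s$lambda, p)
  expect_lt(max(abs(tr$x_filt - (s$v - p$alpha) / p$beta)), 1e-6)
})

test_that("prediction step propagates the AR(1) mean and variance", {
  p <- mixed_params(0.5, 0, 1, 0.3, 1, 0)
  tr <- forward_filter(v = 0, lambda = 0, p, x0 = 2, var0 = 0.8)
  expect_equal(tr$x_pred[1], 1)
  expect_equal(tr$var_pred[1], 0.25 * 0.8 + 0.3)
})

test_that("the reference single-step update matches the grid-posterior argmax", {
  p <- mixed_params(0.9, 0, 1, 0.1, 1, 0)
  # var0 chosen so the one-step-ahead variance is exactly 0.5
  tr <- forward_filter(1, 1, p, x0 = 0, var0 = (0.5 - 0.1) / 0.81)
  want <- oracle_grid_mode(0, 0.5, v = 1, lam = 1, alpha = 0, beta = 1,
                           var_eps = 1, mu = 0)
  expect_lt(abs(tr$x_filt[1] - want), 1e-3)
})

test_that("posterior-mode update equals the grid oracle on random single steps", {
  with_seed(51, {
    for (i in 1:40) {
      rho <- runif(1, 0.5, 0.99)
      alpha <- rnorm(1, 0, 3); beta <- runif(1, 0.3, 3)
      var_eta <- runif(1, 0.01, 0.5); var_eps <- runif(1, 0.2, 3)
      mu <- rnorm(1, -1, 1.5)
      var0 <- runif(1, 0.1, 1)
      x0 <- rnorm(1, 0, 0.5)
      v <- rnorm(1, alpha, 2); lam <- rbinom(1, 1, 0.5)
      p <- mixed_params(rho, alpha, beta, var_eta, var_eps, mu)
      tr <- forward_filter(v, lam, p, x0 = x0, var0 = var0)
      want <- oracle_grid_mode(rho * x0, rho^2 * var0 + var_eta, v, lam,
                               alpha, beta, var_eps, mu)
      expect_lt(abs(tr$x_filt[1] - want), 1e-3)
    }
  })
})

test_that("the forward filter is causal and its track satisfies the variance invariants", {
  s <- simulate_mixed(true_params, 300, seed = 5)
  full <- forward_filter(s$v, s$lambda, true_params)
  part <- forward_filter(s$v[1:120], s$lambda[1:120], true_params)
  expect_identical(full$x_filt[1:120], part$x_filt)
  expect_identical(full$var_filt[1:120], part$var_filt)

  expect_true(all(full$var_filt > 0))
  expect_true(all(full$var_pred >= full$var_filt))
  expect_true(all(full$p > 0 & full$p < 1))
})

test_that("smoother agrees with the textbook RTS oracle in the Gaussian limit", {
  # Bernoulli channel uninformative: mu very negative, lambda all zero
  p <- mixed_params(0.9, 2, 1, 0.2, 0.8, -50)
  with_seed(52, y <- 2 + rnorm(200))
  lam <- rep(0, 200)
  tr <- forward_filter(y, lam, p)
  sm <- mixed_smooth(tr, p)
  okf <- oracle_kf_lg(y, 0.9, 2, 1, 0.2, 0.8, 0, 0.2 / (1 - 0.81))
  osm <- oracle_rts_lg(okf, 0.9)
  expect_equal(tr$x_filt, okf$x_filt, tolerance = 1e-6)
  expect_equal(sm$x_smooth, osm$x_smooth, tolerance = 1e-6)
  expect_equal(sm$var_smooth, osm$var_smooth, tolerance = 1e-6)

  # single step: smoothed == filtered
  tr1 <- forward_filter(y[1], 0, p)
  sm1 <- mixed_smooth(tr1, p)
  expect_equal(sm1$x_smooth, tr1$x_filt)

  # information monotonicity
  expect_true(all(sm$var_smooth <= tr$var_filt + 1e-12))
})

test_that("EM recovers generating parameters on simulated data", {
  s <- simulate_mixed(true_params, 8000, seed = 6)
  fit <- em_fit_mixed(s$v, s$lambda, 0.05)
  expect_lt(abs(fit$params$rho - 0.95), 0.05)
  expect_lt(abs(fit$params$alpha - 10), 0.5)
  expect_lt(abs(fit$params$beta - 2), 0.6)
  expect_lt(abs(fit$params$var_eps / 0.5 - 1), 0.5)
})

test_that("EM started at the truth stays near the truth", {
  s <- simulate_mixed(true_params, 8000, seed = 7)
  fit <- em_fit_mixed(s$v, s$lambda, 0.05, init = true_params)
  expect_lt(abs(fit$params$rho - 0.95), 0.03)
  expect_lt(abs(fit$params$alpha - 10), 0.5)
  expect_lt(abs(fit$params$beta - 2), 0.4)
})

test_that("EM stopping rule and divergence guard behave as specified", {
  s <- simulate_mixed(true_params, 500, seed = 8)
  one <- em_fit_mixed(s$v, s$lambda, 0.05, tol = Inf)
  expect_equal(one$n_iter, 1)
  expect_true(all(vapply(one$params[1:5], is.finite, logical(1))))
})

test_that("each M-step does not decrease the expected complete-data log-likelihood", {
  for (seed in c(9, 10)) {
    s <- simulate_mixed(true_params, 2000, seed = seed)
    fit <- em_fit_mixed(s$v, s$lambda, 0.05, max_iter = 60)
    expect_true(all(fit$q_steps$q_new >= fit$q_steps$q_old - 1e-6))
  }
})

test_that("filter, smoother and EM match the linear-Gaussian oracle chain when the binary channel is uninformative", {
  p0 <- list(rho = 0.85, alpha = 3, beta = 1.5, var_eta = 0.3, var_eps = 1)
  with_seed(53, {
    x <- as.numeric(arima.sim(list(ar = 0.85), 600, sd = sqrt(0.3)))
    y <- 3 + 1.5 * x + rnorm(600)
  })
  lam <- rep(0, 600)
  mu_off <- -40                       # logistic term numerically zero
  init <- mixed_params(p0$rho, p0$alpha, p0$beta, p0$var_eta, p0$var_eps,
                       mu_off)
  fit <- em_fit_mixed(y, lam, logistic_prob(mu_off, 0), init = init,
                      tol = 0, max_iter = 12)
  want <- oracle_em_lg(y, p0$rho, p0$alpha, p0$beta, p0$var_eta,
                       p0$var_eps, n_iter = 12)
  expect_equal(fit$params$rho, want$rho, tolerance = 1e-6)
  expect_equal(fit$params$alpha, want$alpha, tolerance = 1e-6)
  expect_equal(fit$params$beta, want$beta, tolerance = 1e-6)
  expect_equal(fit$params$var_eta, want$var_eta, tolerance = 1e-6)
  expect_equal(fit$params$var_eps, want$var_eps, tolerance = 1e-6)
})
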