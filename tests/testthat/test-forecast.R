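test_that("random walk with drift fits exact and degenerate series", {
  m <- fit_kt_model(c(-2, -1, 0, 1, 2))
  expect_equal(m$drift, 1)
  expect_equal(m$sigma, 0)
  m0 <- fit_kt_model(rep(3, 6))
  expect_equal(m0$drift, 0)
  expect_equal(m0$sigma, 0)
  expect_error(fit_kt_model(1:3), "at least 4")
})

test_that("drift estimate is consistent on a long simulated walk", {
  set.seed(101)
  n <- 500; drift <- 0.5; sigma <- 0.2
  k <- cumsum(c(0, drift + sigma * rnorm(n - 1)))
  m <- fit_kt_model(k)
  se_drift <- m$sigma / sqrt(n - 1)
  expect_lt(abs(m$drift - drift), 3 * se_drift)
  expect_lt(abs(m$sigma - sigma) / sigma, 0.2)
})

test_that("index forecasts continue the walk with the documented standard errors", {
  k <- c(-2, -1, 0, 1, 2)
  fc <- forecast_kt(fit_kt_model(k), horizon = 4)
  expect_equal(fc$k_hat, 2 + 1:4)
  expect_equal(fc$se_k, rep(0, 4))

  set.seed(111)
  k2 <- cumsum(c(0, -0.5 + 0.3 * rnorm(29)))
  m2 <- fit_kt_model(k2)
  n <- length(k2)
  fc2 <- forecast_kt(m2, 5, se_method = "drift")
  expect_equal(fc2$se_k, m2$sigma * sqrt(1:5 + (1:5)^2 / (n - 1)))
  # pure-innovation convention at h = 1 is just sigma
  fc3 <- forecast_kt(m2, 5, se_method = "innovation")
  expect_equal(fc3$se_k[1], m2$sigma)
  expect_equal(fc3$se_k, m2$sigma * sqrt(1:5))
  # widening in h for both conventions
  expect_true(all(diff(fc2$se_k) > 0))
  expect_true(all(diff(fc3$se_k) > 0))
})

test_that("rate projection anchors on the jump-off and is log-symmetric", {
  p <- lc_parameters(a_x = c(-9, -8), b_x = c(0.3, 0.7), k_t = c(-1, 0, 1))
  jump <- c(0.001, 0.004)

  # zero index change: the forecast is the jump-off rates for every age
  kfc0 <- structure(list(horizon = 3L, k_hat = rep(1, 3), se_k = rep(0.2, 3),
                         drift = 0, sigma = 0.2, model_order = c(0L, 1L, 0L),
                         k_last = 1), class = "kt_forecast")
  rf0 <- forecast_rates(p, kfc0, jump)
  expect_equal(unname(rf0$rates), matrix(jump, 2, 3))
  # log-scale interval symmetry, exact
  expect_equal(log(rf0$upper) - log(rf0$rates), log(rf0$rates) - log(rf0$lower))
  expect_true(all(rf0$lower <= rf0$rates & rf0$rates <= rf0$upper))

  # hand-checked arithmetic: b = 0.2, k moves 0 -> 1, m = 0.01, se = 0.5
  ph <- lc_parameters(a_x = c(-5, -5), b_x = c(0.2, 0.8), k_t = c(-0.5, 0.5))
  kfc1 <- structure(list(horizon = 1L, k_hat = 1, se_k = 0.5,
                         drift = 0.5, sigma = 0, model_order = c(0L, 1L, 0L),
                         k_last = 0.5), class = "kt_forecast")
  rf1 <- forecast_rates(ph, kfc1, c(0.01, 0.01))
  expect_equal(rf1$rates[1, 1], 0.01 * exp(0.2 * 0.5))
  expect_equal(rf1$upper[1, 1], rf1$rates[1, 1] * exp(2 * 0.2 * 0.5))
  expect_equal(rf1$lower[1, 1], rf1$rates[1, 1] * exp(-2 * 0.2 * 0.5))

  # an insensitive age (b = 0) stays at its jump-off with a degenerate interval
  pz <- lc_parameters(a_x = c(-9, -8), b_x = c(0, 1), k_t = c(-1, 1))
  rfz <- forecast_rates(pz, kfc1, jump)
  expect_equal(unname(rfz$rates[1, ]), jump[1])
  expect_equal(rfz$lower[1, ], rfz$upper[1, ])

  expect_error(forecast_rates(p, kfc0, c(0, 0.01)), "positive")
})

test_that("chained one-step forecasts equal the direct h-step forecast", {
  set.seed(121)
  k <- cumsum(c(0, -0.4 + 0.25 * rnorm(24)))
  fit <- lee_carter(make_rank1_surface(runif(5, -10, -8),
                                       {b <- runif(5); b / sum(b)},
                                       k - mean(k), first_age = 25))
  direct <- predict(fit, h = 6)
  m <- fit_kt_model(fit$kt)
  # chain the index one drift step at a time
  chained <- fit$kt[length(fit$kt)] + cumsum(rep(m$drift, 6))
  expect_equal(direct$kt$k_hat, chained)
  # and the rate identity telescopes the same way
  jump <- fit$surface$rates[, ncol(fit$surface$rates)]
  step_rates <- jump
  for (h in 1:6)
    step_rates <- step_rates * exp(fit$bx * m$drift)
  expect_equal(unname(direct$rates[, 6]), unname(step_rates))
})

test_that("a common index change distributes across ages according to sum(b) = 1", {
  set.seed(131)
  truth <- random_abk(6, 20)
  fit <- lee_carter(make_rank1_surface(truth$a, truth$b, truth$k))
  fc <- predict(fit, h = 3)
  jump <- fit$surface$rates[, 20]
  for (h in 1:3) {
    delta <- fc$kt$k_hat[h] - fit$kt[20]
    expect_equal(sum(log(fc$rates[, h] / jump)), delta)
  }
})

test_that("the two-sigma index band covers the truth at nominal-ish rates", {
  set.seed(141)
  n <- 30; h <- 5; drift <- -0.5; sigma <- 0.3
  hits <- logical(500)
  for (i in seq_len(500)) {
    steps <- drift + sigma * rnorm(n + h - 1)
    k <- cumsum(c(0, steps))
    m <- fit_kt_model(k[1:n])
    fc <- forecast_kt(m, h, se_method = "drift")
    hits[i] <- abs(k[n + h] - fc$k_hat[h]) <= 2 * fc$se_k[h]
  }
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("non-default ARIMA orders are delegated behind the same contract", {
  set.seed(151)
  k <- cumsum(c(0, -0.3 + 0.2 * rnorm(39)))
  m <- fit_kt_model(k, order = c(0, 1, 1))
  fc <- forecast_kt(m, 5)
  expect_length(fc$k_hat, 5)
  expect_true(all(diff(fc$se_k) >= 0))
  expect_equal(fc$model_order, c(0L, 1L, 1L))
})
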