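test_that("age level is the row mean of log-rates", {
  m <- matrix(c(-4, -6, -2, -4), 2, 2)
  expect_equal(estimate_ax(m), c(-3, -5))
  expect_equal(estimate_ax(matrix(-7, 3, 4)), rep(-7, 3))
  set.seed(21)
  big <- matrix(rnorm(7 * 30, -9), 7, 30)
  expect_equal(estimate_ax(big), oracle_row_means(big), tolerance = 1e-12)
  expect_error(estimate_ax(matrix(numeric(0), 0, 0)), "empty")
})

test_that("SVD stage exactly recovers a noiseless constrained triple", {
  set.seed(31)
  for (drift_sign in c(-1, 1)) {
    truth <- random_abk(7, 30)
    truth$k <- truth$k + drift_sign * seq(-3, 3, length.out = 30)
    truth$k <- truth$k - mean(truth$k)
    s <- make_rank1_surface(truth$a, truth$b, truth$k)
    ls <- to_log_surface(s)
    p <- estimate_bk_svd(ls, estimate_ax(ls))
    expect_lt(max(abs(p$a_x - truth$a)), 1e-8)
    expect_lt(max(abs(p$b_x - truth$b)), 1e-8)
    expect_lt(max(abs(p$k_t - truth$k)), 1e-8)
    diag <- fitted_and_residuals(ls, p)
    expect_equal(diag$percent_variation, 1, tolerance = 1e-10)
    expect_lt(max(abs(diag$residuals)), 1e-8)
  }
})

test_that("identification constraints hold after every estimation path", {
  set.seed(41)
  for (rep in 1:5) {
    spec <- sim_spec(seed = 40 + rep)
    s <- simulate_surface(spec)
    ls <- to_log_surface(s)
    p1 <- estimate_bk_svd(ls)
    expect_lt(abs(sum(p1$b_x) - 1), 1e-10)
    expect_lt(abs(sum(p1$k_t)), 1e-10)
    p2 <- reestimate_kt(p1, s)
    expect_lt(abs(sum(p2$b_x) - 1), 1e-10)
    expect_lt(abs(sum(p2$k_t)), 1e-10)
    # sign convention: b sums to +1, never -1
    expect_equal(sum(p2$b_x), 1, tolerance = 1e-10)
  }
})

test_that("degenerate centred surface returns the documented uniform convention", {
  s <- mortality_surface(c(50, 55, 60), 2000:2004,
                         rates = matrix(exp(-8), 3, 5),
                         exposures = matrix(1e5, 3, 5))
  p <- estimate_bk_svd(to_log_surface(s))
  expect_equal(p$b_x, rep(1 / 3, 3))
  expect_equal(p$k_t, rep(0, 5))
  expect_equal(p$a_x, rep(-8, 3))
})

test_that("rank-1 SVD fit attains the constrained least-squares optimum", {
  set.seed(51)
  for (dims in list(c(5, 8), c(8, 12))) {
    for (rep in 1:10) {
      f <- matrix(rnorm(prod(dims), -9, 0.5), dims[1], dims[2])
      p <- estimate_bk_svd(f, estimate_ax(f))
      rss_svd <- sum((f - outer(p$a_x, rep(1, dims[2])) -
                        outer(p$b_x, p$k_t))^2)
      rss_opt <- oracle_rank1_rss(f)
      expect_lt(abs(rss_svd - rss_opt) / rss_svd, 1e-6)
    }
  }
})

test_that("re-estimation matches yearly death totals and fixes nothing it should not", {
  # noiseless surface: re-estimation is a fixed point
  set.seed(61)
  truth <- random_abk(7, 30)
  s <- make_rank1_surface(truth$a, truth$b, truth$k)
  ls <- to_log_surface(s)
  p1 <- estimate_bk_svd(ls)
  p2 <- reestimate_kt(p1, s)
  expect_lt(max(abs(p2$k_t - p1$k_t)), 1e-8)
  expect_lt(max(abs(p2$a_x - p1$a_x)), 1e-8)

  # Poisson noise: after re-estimation the model reproduces observed totals
  sp <- simulate_surface(sim_spec(seed = 62))
  pp <- reestimate_kt(estimate_bk_svd(to_log_surface(sp)), sp)
  implied <- colSums(sp$exposures * exp(outer(pp$a_x, rep(1, 30)) +
                                          outer(pp$b_x, pp$k_t)))
  expect_lt(max(abs(implied - colSums(sp$deaths)) / colSums(sp$deaths)), 1e-8)
})

test_that("single-age re-estimation matches the closed form", {
  # r = 1: a + k = ln(D_t / N_t) exactly (b = 1)
  n <- 12
  k <- seq(-2, 2, length.out = n); k <- k - mean(k)
  a <- -9
  N <- matrix(5e5, 1, n)
  D <- as.vector(N) * exp(a + k)
  p1 <- lc_parameters(a_x = a, b_x = 1, k_t = k, years = seq_len(n))
  p2 <- reestimate_kt(p1, D, N)
  expect_equal(p2$a_x + p2$k_t, log(D / as.vector(N)), tolerance = 1e-10)
})

test_that("with positive b the total-death equation is strictly increasing in k", {
  set.seed(71)
  for (rep in 1:100) {
    r <- sample(2:8, 1)
    b <- runif(r); b <- b / sum(b)
    a <- runif(r, -10, -6)
    N <- runif(r, 1e4, 1e6)
    ks <- sort(runif(5, -10, 10))
    g <- vapply(ks, function(k) sum(N * exp(a + b * k)), numeric(1))
    expect_true(all(diff(g) > 0))
  }
})

test_that("parameters are recovered under Poisson noise at realistic exposure", {
  for (seed in 1:3) {
    spec <- sim_spec(seed = seed)
    truth <- generate_true_parameters(spec)
    s <- simulate_surface(spec, truth)
    fit <- lee_carter(s)
    expect_gt(cor(fit$kt, truth$k_t), 0.99)
    expect_lt(max(abs(fit$bx - truth$b_x)), 0.05)
  }
})

test_that("fitted + residuals reproduce the observed surface; PV follows the spectrum", {
  s <- simulate_surface(sim_spec(seed = 81))
  ls <- to_log_surface(s)
  p <- estimate_bk_svd(ls)
  d <- fitted_and_residuals(ls, p)
  expect_equal(d$fitted_log + d$residuals, ls$values)
  expect_true(d$percent_variation >= 0 && d$percent_variation <= 1)

  # PV arithmetic on a known spectrum (2, 1, 1) -> 4/6
  pk <- lc_parameters(a_x = c(0, 0, 0), b_x = rep(1 / 3, 3), k_t = c(-1, 0, 1),
                      singular_values = c(2, 1, 1))
  dk <- fitted_and_residuals(matrix(0, 3, 3), pk)
  expect_equal(dk$percent_variation, 4 / 6)

  # true parameters carry no spectrum: PV is reported as missing
  ptrue <- generate_true_parameters(sim_spec(seed = 1))
  strue <- simulate_surface(sim_spec(seed = 1, noise_model = "none"), ptrue)
  expect_true(is.na(fitted_and_residuals(to_log_surface(strue),
                                         ptrue)$percent_variation))
})

test_that("lc_parameters rejects violated constraints", {
  expect_error(lc_parameters(a_x = 1, b_x = 0.5, k_t = 0), "sum\\(b_x\\)")
  expect_error(lc_parameters(a_x = 1, b_x = 1, k_t = c(1, 1)), "sum\\(k_t\\)")
})
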