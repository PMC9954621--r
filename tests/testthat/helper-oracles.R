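# Independent oracles and fixture builders. Everything here is coded
# straightforwardly and separately from the package internals it checks.

# Build a noiseless surface from a known constrained (a, b, k) triple.
make_rank1_surface <- function(a, b, k, exposure = 1e6, first_year = 1990,
                               first_age = 50, width = 5) {
  stopifnot(abs(sum(b) - 1) < 1e-12, abs(sum(k)) < 1e-10)
  rates <- exp(outer(a, rep(1, length(k))) + outer(b, k))
  mortality_surface(ages = first_age + width * (seq_along(a) - 1L),
                    years = first_year + seq_along(k) - 1L,
                    rates = rates,
                    exposures = matrix(exposure, length(a), length(k)),
                    widths = rep(width, length(a)))
}

# Random constrained parameter triple (positive b).
random_abk <- function(r, n) {
  a <- runif(r, -11, -8)
  b <- runif(r, 0.2, 1); b <- b / sum(b)
  k <- cumsum(rnorm(n)); k <- k - mean(k)
  list(a = a, b = b, k = k)
}

# Row means by explicit loop.
oracle_row_means <- function(m) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- 0
    for (j in seq_len(ncol(m))) s <- s + m[i, j]
    out[i] <- s / ncol(m)
  }
  out
}

# Constrained rank-1 least squares by direct numerical minimisation (BFGS
# with analytic gradient). Minimises sum((f - a - b k')^2) over b (sum 1)
# and k, with the level a absorbed optimally; returns the attained RSS.
oracle_rank1_rss <- function(f) {
  r <- nrow(f); n <- ncol(f)
  C <- f - oracle_row_means(f)      # optimal a given (b, centred k)
  obj <- function(par) {
    bf <- par[seq_len(r - 1)]
    b <- c(bf, 1 - sum(bf))
    k <- par[r:(r + n - 1)]
    sum((C - outer(b, k))^2)
  }
  grad <- function(par) {
    bf <- par[seq_len(r - 1)]
    b <- c(bf, 1 - sum(bf))
    k <- par[r:(r + n - 1)]
    R <- C - outer(b, k)
    gb <- -2 * as.vector(R %*% k)
    gk <- -2 * as.vector(t(R) %*% b)
    c(gb[seq_len(r - 1)] - gb[r], gk)
  }
  b0 <- rep(1 / r, r)
  k0 <- as.vector(t(C) %*% b0) / sum(b0^2)
  fit <- optim(c(b0[seq_len(r - 1)], k0), obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  fit$value
}

# Abridged life table by direct summation, coded independently.
oracle_e0 <- function(m, widths, a = 0.5, radix = 1e5) {
  ng <- length(m)
  a <- rep_len(a, ng); widths <- rep_len(widths, ng)
  l <- radix
  total_years <- 0
  for (i in seq_len(ng)) {
    if (i < ng) {
      q <- widths[i] * m[i] / (1 + widths[i] * (1 - a[i]) * m[i])
      q <- min(q, 1)
      d <- l * q
      total_years <- total_years + widths[i] * (l - d) + a[i] * widths[i] * d
      l <- l - d
    } else {
      total_years <- total_years + l / m[i]
    }
  }
  total_years / radix
}

# Error-table aggregation by explicit loops.
oracle_error_report <- function(actual, predicted) {
  e <- (actual - predicted) / actual
  r <- nrow(e); n <- ncol(e)
  mpe <- mape_a <- numeric(r)
  for (i in seq_len(r)) {
    mpe[i] <- sum(e[i, ]) / n
    mape_a[i] <- sum(abs(e[i, ])) / n
  }
  ipe <- iape <- numeric(n)
  for (j in seq_len(n)) {
    ipe[j] <- sum(e[, j]) / r
    iape[j] <- sum(abs(e[, j])) / r
  }
  list(mpe = mpe, mape = mape_a, ipe = ipe, iape = iape,
       overall = mean(abs(e)) * 100)
}
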