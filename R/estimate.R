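#' Lee-Carter parameter set
#'
#' Container for a \code{(a_x, b_x, k_t)} triple under the identifiability
#' restrictions \code{sum(b_x) = 1} and \code{sum(k_t) = 0}, together with the
#' singular values of the centred log-surface when the triple came from an
#' SVD fit (empty for true/simulated parameters).
#'
#' @param a_x mean log-mortality by age (length r).
#' @param b_x age sensitivities (length r), summing to 1.
#' @param k_t mortality index by year (length n), summing to 0.
#' @param singular_values singular values of the centred log-surface, or
#'   \code{numeric(0)}.
#' @param ages,years labels carried from the source surface.
#' @return Object of class \code{"lc_parameters"}.
#' @export
lc_parameters <- function(a_x, b_x, k_t, singular_values = numeric(0),
                          ages = seq_along(a_x), years = seq_along(k_t)) {
  a_x <- as.numeric(a_x); b_x <- as.numeric(b_x); k_t <- as.numeric(k_t)
  if (length(a_x) != length(b_x))
    stop("lc_parameters: a_x and b_x lengths differ")
  if (length(ages) != length(a_x) || length(years) != length(k_t))
    stop("lc_parameters: label lengths do not match parameters")
  if (abs(sum(b_x) - 1) > 1e-10)
    stop("lc_parameters: sum(b_x) must equal 1 (got ", sum(b_x), ")")
  if (abs(sum(k_t)) > 1e-10 * max(1, max(abs(k_t))))
    stop("lc_parameters: sum(k_t) must equal 0 (got ", sum(k_t), ")")
  structure(list(a_x = a_x, b_x = b_x, k_t = k_t,
                 singular_values = as.numeric(singular_values),
                 ages = ages, years = years),
            class = "lc_parameters")
}

#' @export
print.lc_parameters <- function(x, ...) {
  cat(sprintf("Lee-Carter parameters: %d age groups, %d years\n",
              length(x$a_x), length(x$k_t)))
  cat(sprintf("  a_x in [%.3f, %.3f];  b_x in [%.4f, %.4f] (sum %.6f)\n",
              min(x$a_x), max(x$a_x), min(x$b_x), max(x$b_x), sum(x$b_x)))
  cat(sprintf("  k_t from %.3f to %.3f (sum %.2e)\n",
              x$k_t[1], x$k_t[length(x$k_t)], sum(x$k_t)))
  if (length(x$singular_values))
    cat(sprintf("  leading singular value %.4f (PV %.1f%%)\n",
                x$singular_values[1],
                100 * x$singular_values[1]^2 / sum(x$singular_values^2)))
  invisible(x)
}

#' Age level: mean log-rate by age
#'
#' First Lee-Carter estimate: \code{a_x} is the arithmetic mean of the
#' log-rate of each age group across years.
#'
#' @param logsurf a [to_log_surface()] object, or a bare log-rate matrix.
#' @return Numeric vector of length r (number of age groups).
#' @export
estimate_ax <- function(logsurf) {
  v <- if (inherits(logsurf, "log_surface")) logsurf$values else as.matrix(logsurf)
  if (length(v) == 0L) stop("estimate_ax: empty surface")
  if (!all(is.finite(v))) stop("estimate_ax: log-surface has non-finite cells")
  rowMeans(v)
}

#' Age sensitivity and mortality index via rank-1 SVD
#'
#' Forms the centred surface \code{D* = logsurf - a_x} (subtracting the age
#' level from each row), takes the leading singular triple
#' \code{(s1, u1, v1)}, and normalises it to the Lee-Carter identification:
#' \code{b_x = u1 / sum(u1)} and \code{k_t = s1 * sum(u1) * v1}, so that
#' \code{b_x \%o\% k_t = s1 * u1 \%o\% v1} and \code{sum(b_x) = 1}. The index
#' is then centred to mean zero with the offset absorbed into \code{a_x},
#' which leaves fitted log-rates unchanged. All singular values are stored so
#' the percentage of variation \code{s1^2 / sum(s^2)} can be reported.
#'
#' An exactly zero centred surface is degenerate (any direction fits equally
#' well); the documented convention \code{b_x = 1/r}, \code{k_t = 0} is
#' returned. A leading age vector summing to zero cannot be normalised and is
#' an error.
#'
#' @param logsurf a [to_log_surface()] object or log-rate matrix.
#' @param a_x age level, usually from [estimate_ax()].
#' @return An [lc_parameters()] object.
#' @export
estimate_bk_svd <- function(logsurf, a_x = estimate_ax(logsurf)) {
  v <- if (inherits(logsurf, "log_surface")) logsurf$values else as.matrix(logsurf)
  r <- nrow(v); n <- ncol(v)
  if (length(a_x) != r) stop("estimate_bk_svd: a_x length must match rows")
  ages <- if (inherits(logsurf, "log_surface")) logsurf$ages else seq_len(r)
  years <- if (inherits(logsurf, "log_surface")) logsurf$years else seq_len(n)
  dstar <- v - a_x
  if (all(abs(dstar) < 1e-14))
    return(lc_parameters(a_x = a_x, b_x = rep(1 / r, r), k_t = rep(0, n),
                         singular_values = rep(0, min(r, n)),
                         ages = ages, years = years))
  sv <- svd(dstar)
  u1 <- sv$u[, 1]; v1 <- sv$v[, 1]; s1 <- sv$d[1]
  su <- sum(u1)
  if (abs(su) < sqrt(.Machine$double.eps))
    stop("estimate_bk_svd estimation error: leading age vector sums to ~0; ",
         "b_x cannot be normalised to sum 1")
  b <- u1 / su
  k <- s1 * su * v1
  # restore sum(k) = 0, folding the shift into the age level
  kbar <- mean(k)
  lc_parameters(a_x = a_x + b * kbar, b_x = b, k_t = k - kbar,
                singular_values = sv$d, ages = ages, years = years)
}

#' Second-stage re-estimation of the mortality index
#'
#' Adjusts each year's index so that the model-implied total deaths match the
#' observed total: \code{k_t} is replaced by the root of
#' \deqn{g(k) = \sum_x N_{x,t} \exp(a_x + b_x k) - D_t,}
#' found independently per year by bracketed root-finding (residuals are
#' treated as zero). The first-stage \code{k_t} seeds the bracket, which is
#' expanded symmetrically (start +/- 10, doubling, at most 2^10 expansions)
#' until \code{g} changes sign. When every \code{b_x > 0}, \code{g} is
#' strictly increasing and the root unique; with mixed-sign \code{b_x} and
#' multiple sign changes, the root nearest the first-stage value is kept and
#' a warning issued. Afterwards the index is re-centred to mean zero with the
#' shift absorbed into \code{a_x}, so fitted values are untouched and the
#' identification constraints hold again.
#'
#' @param params first-stage [lc_parameters()].
#' @param deaths_total observed total deaths per year (length n), or a
#'   [mortality_surface()] from which totals and exposures are taken.
#' @param exposures age-by-year exposure matrix (ignored when a surface is
#'   given).
#' @param tol relative convergence tolerance for the root (default 1e-10).
#' @return An [lc_parameters()] with adjusted \code{a_x}, \code{k_t}; the
#'   first-stage singular values are carried over.
#' @export
reestimate_kt <- function(params, deaths_total, exposures = NULL, tol = 1e-10) {
  stopifnot(inherits(params, "lc_parameters"))
  if (inherits(deaths_total, "mortality_surface")) {
    exposures <- deaths_total$exposures
    deaths_total <- colSums(deaths_total$deaths)
  }
  n <- length(params$k_t); r <- length(params$a_x)
  if (length(deaths_total) != n)
    stop("reestimate_kt: deaths_total length must equal the number of years")
  exposures <- as.matrix(exposures)
  if (!all(dim(exposures) == c(r, n)) || any(exposures <= 0))
    stop("reestimate_kt: exposures must be a positive r x n matrix")
  a <- params$a_x; b <- params$b_x
  k_new <- numeric(n)
  mixed_sign <- any(b > 0) && any(b < 0)
  for (t in seq_len(n)) {
    Dt <- deaths_total[t]
    Nt <- exposures[, t]
    g <- function(k) sum(Nt * exp(a + b * k)) - Dt
    k0 <- params$k_t[t]
    half <- 10
    lo <- k0 - half; hi <- k0 + half
    expansions <- 0L
    while (sign(g(lo)) == sign(g(hi))) {
      expansions <- expansions + 1L
      if (expansions > 10L)
        stop(sprintf(paste0("reestimate_kt estimation error: no sign change ",
                            "bracketing year %s after %d expansions"),
                     params$years[t], expansions - 1L))
      half <- half * 2
      lo <- k0 - half; hi <- k0 + half
    }
    root <- stats::uniroot(g, c(lo, hi), tol = tol * max(1, abs(k0)))$root
    # polish with a few Newton steps: g'(k) = sum(Nt * b * exp(a + b k))
    for (it in 1:8) {
      gr <- sum(Nt * b * exp(a + b * root))
      if (gr == 0) break
      step <- g(root) / gr
      root <- root - step
      if (abs(step) < 1e-14 * max(1, abs(root))) break
    }
    if (mixed_sign) {
      # scan for additional roots; keep the one closest to the first stage
      grid <- seq(k0 - 2 * half, k0 + 2 * half, length.out = 512)
      gg <- vapply(grid, g, numeric(1))
      flips <- which(gg[-1] * gg[-length(gg)] < 0)
      if (length(flips) > 1L) {
        roots <- vapply(flips, function(i)
          stats::uniroot(g, grid[c(i, i + 1)], tol = tol)$root, numeric(1))
        root <- roots[which.min(abs(roots - k0))]
        warning("reestimate_kt: multiple roots with mixed-sign b_x; ",
                "keeping the root nearest the first-stage k_t")
      }
    }
    k_new[t] <- root
  }
  kbar <- mean(k_new)
  lc_parameters(a_x = a + b * kbar, b_x = b, k_t = k_new - kbar,
                singular_values = params$singular_values,
                ages = params$ages, years = params$years)
}

#' Fitted log-rates, residuals and percentage of variation
#'
#' Computes the model surface \code{a_x + b_x k_t}, the residual surface
#' (observed minus fitted log-rates, the \code{e_{x,t}} term of the model),
#' and the percentage of variation captured by the rank-1 fit,
#' \code{s1^2 / sum(s_i^2)} from the stored singular values (\code{NA} when
#' the parameters did not come from an SVD).
#'
#' @param logsurf observed log-surface ([to_log_surface()] or matrix).
#' @param params an [lc_parameters()].
#' @return Object of class \code{"lc_diagnostics"}: list with
#'   \code{fitted_log}, \code{residuals}, \code{percent_variation} (fraction
#'   in \code{[0, 1]} or \code{NA}).
#' @export
fitted_and_residuals <- function(logsurf, params) {
  stopifnot(inherits(params, "lc_parameters"))
  v <- if (inherits(logsurf, "log_surface")) logsurf$values else as.matrix(logsurf)
  r <- length(params$a_x); n <- length(params$k_t)
  if (!all(dim(v) == c(r, n)))
    stop("fitted_and_residuals: surface and parameter dimensions disagree")
  fit <- outer(params$a_x, rep(1, n)) + outer(params$b_x, params$k_t)
  dimnames(fit) <- dimnames(v)
  pv <- if (length(params$singular_values))
    params$singular_values[1]^2 / sum(params$singular_values^2) else NA_real_
  structure(list(fitted_log = fit, residuals = v - fit,
                 percent_variation = pv),
            class = "lc_diagnostics")
}
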