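#' Fit the Lee-Carter model to a mortality surface
#'
#' Fits the log-bilinear model \code{ln m[x, t] = a_x + b_x k_t + e[x, t]}
#' under the identification constraints \code{sum(b_x) = 1},
#' \code{sum(k_t) = 0}, by the classical two-stage procedure:
#' \enumerate{
#'   \item \code{a_x} as row means of the log-rates; \code{b_x}, \code{k_t}
#'     from the rank-1 singular value decomposition of the row-centred
#'     log-surface ([estimate_ax()], [estimate_bk_svd()]);
#'   \item optional re-estimation of each \code{k_t} so model-implied total
#'     deaths equal the observed yearly totals ([reestimate_kt()]).
#' }
#'
#' @param surface a [mortality_surface()].
#' @param zero_floor floor applied to zero rates before taking logs
#'   (per person-year); see [to_log_surface()].
#' @param reestimate logical: run the second stage? Default \code{TRUE}.
#' @return Object of class \code{"lee_carter"}: list with components
#'   \describe{
#'     \item{ax, bx, kt}{fitted parameters (after re-estimation if requested).}
#'     \item{params}{the same triple as an [lc_parameters()] object.}
#'     \item{first_stage}{the pure-SVD [lc_parameters()].}
#'     \item{singular_values, percent_variation}{SVD spectrum of the centred
#'       log-surface and the share of its variation captured by the first
#'       component.}
#'     \item{fitted_log, residuals}{fitted log-rates and residual surface.}
#'     \item{surface, logsurf}{the training data.}
#'   }
#' @seealso [predict.lee_carter()] for forecasting, [lc_accuracy()] for error
#'   measures, [life_table()] for life expectancy.
#' @examples
#' fit <- lee_carter(simulate_surface(sim_spec(seed = 7)))
#' fit
#' coef(fit)$b_x
#' @export
lee_carter <- function(surface, zero_floor = 1e-8, reestimate = TRUE) {
  stopifnot(inherits(surface, "mortality_surface"))
  ls <- to_log_surface(surface, zero_floor)
  first <- estimate_bk_svd(ls, estimate_ax(ls))
  params <- if (reestimate) reestimate_kt(first, surface) else first
  diag <- fitted_and_residuals(ls, params)
  pv <- first$singular_values[1]^2 / sum(first$singular_values^2)
  structure(list(ax = params$a_x, bx = params$b_x, kt = params$k_t,
                 params = params, first_stage = first,
                 singular_values = first$singular_values,
                 percent_variation = pv,
                 fitted_log = diag$fitted_log, residuals = diag$residuals,
                 surface = surface, logsurf = ls,
                 reestimated = reestimate,
                 call = match.call()),
            class = "lee_carter")
}

#' @export
print.lee_carter <- function(x, ...) {
  cat("Lee-Carter mortality model\n")
  cat(sprintf("  data: %s%d age groups x %d years (%d-%d)\n",
              if (nzchar(x$surface$label)) paste0(x$surface$label, ", ") else "",
              length(x$ax), length(x$kt),
              min(x$surface$years), max(x$surface$years)))
  cat(sprintf("  percentage of variation (first SVD component): %.1f%%\n",
              100 * x$percent_variation))
  cat(sprintf("  k_t: %.3f -> %.3f%s\n", x$kt[1], x$kt[length(x$kt)],
              if (x$reestimated) "  (re-estimated to match yearly death totals)" else ""))
  invisible(x)
}

#' @export
summary.lee_carter <- function(object, ...) {
  drift <- mean(diff(object$kt))
  res <- object$residuals
  structure(list(label = object$surface$label,
                 n_ages = length(object$ax), n_years = length(object$kt),
                 years = range(object$surface$years),
                 percent_variation = object$percent_variation,
                 drift = drift,
                 constraint_b = sum(object$bx) - 1,
                 constraint_k = sum(object$kt),
                 resid_sd = stats::sd(as.vector(res)),
                 mape_within = mape(object$surface$rates, exp(object$fitted_log)),
                 coef_table = data.frame(age = object$surface$ages,
                                         a_x = object$ax, b_x = object$bx)),
            class = "summary.lee_carter")
}

#' @export
print.summary.lee_carter <- function(x, ...) {
  cat(sprintf("Lee-Carter fit%s: %d ages x %d years (%d-%d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_ages, x$n_years, x$years[1], x$years[2]))
  cat(sprintf("  percentage of variation: %.2f%%\n", 100 * x$percent_variation))
  cat(sprintf("  k_t drift (mean annual change): %.4f\n", x$drift))
  cat(sprintf("  within-sample MAPE of rates: %.4f%%\n", x$mape_within))
  cat(sprintf("  residual log-rate SD: %.5f\n", x$resid_sd))
  cat(sprintf("  constraint residuals: sum(b)-1 = %.2e, sum(k) = %.2e\n",
              x$constraint_b, x$constraint_k))
  cat("\nAge coefficients:\n")
  print(x$coef_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.lee_carter <- function(object, ...) {
  list(a_x = object$ax, b_x = object$bx, k_t = object$kt)
}

#' @export
fitted.lee_carter <- function(object, type = c("rate", "log"), ...) {
  type <- match.arg(type)
  if (type == "log") object$fitted_log else exp(object$fitted_log)
}

#' @export
residuals.lee_carter <- function(object, ...) object$residuals

#' Plot a Lee-Carter fit
#'
#' Three panels in the conventional layout: the age level \code{a_x}, the age
#' sensitivity \code{b_x}, and the mortality index \code{k_t} over calendar
#' time.
#'
#' @param x a \code{"lee_carter"} fit.
#' @param ... passed to the individual \code{plot} calls.
#' @return \code{x}, invisibly.
#' @export
plot.lee_carter <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ages <- x$surface$ages; years <- x$surface$years
  plot(ages, x$ax, type = "b", xlab = "age", ylab = expression(a[x]),
       main = "age level", ...)
  plot(ages, x$bx, type = "b", xlab = "age", ylab = expression(b[x]),
       main = "age sensitivity", ...)
  plot(years, x$kt, type = "l", xlab = "year", ylab = expression(k[t]),
       main = "mortality index", ...)
  invisible(x)
}

#' Simulate surfaces from a fitted Lee-Carter model
#'
#' Draws new death-count surfaces with Poisson noise around the fitted rates
#' and the training exposures — a parametric-bootstrap style check of the
#' fitted model.
#'
#' @param object a \code{"lee_carter"} fit.
#' @param nsim number of surfaces to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of \code{nsim} [mortality_surface()] objects.
#' @export
simulate.lee_carter <- function(object, nsim = 1, seed = NULL, ...) {
  surf <- object$surface
  mu <- exp(object$fitted_log)
  lam <- mu * surf$exposures
  draw <- function(i) {
    deaths <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    mortality_surface(surf$ages, surf$years, deaths = deaths,
                      exposures = surf$exposures, widths = surf$widths,
                      label = paste0(surf$label, " (simulated)"))
  }
  if (!is.null(seed)) {
    out <- .with_sim_seed(as.integer(seed), 0L, lapply(seq_len(nsim), draw))
  } else out <- lapply(seq_len(nsim), draw)
  out
}

#' Forecast death rates from a fitted Lee-Carter model
#'
#' Projects the mortality index \code{h} years ahead with a random walk with
#' drift (or another ARIMA order via \code{order}), then converts index
#' forecasts to age-specific rates anchored on the jump-off rates:
#' \deqn{\hat m_{x,n+h} = m_{x,n} \exp\{\hat b_x (\hat k_{n+h} - \hat k_n)\},}
#' with the approximate interval
#' \eqn{\hat m \exp(\pm 2 \hat b_x \, \mathrm{se}_{k,h})}.
#'
#' @param object a \code{"lee_carter"} fit.
#' @param h forecast horizon in years.
#' @param order ARIMA order for the index model; default \code{c(0, 1, 0)}
#'   plus drift (random walk with drift).
#' @param se_method \code{"drift"} (innovation plus drift-estimation
#'   uncertainty, the default) or \code{"innovation"} (pure h*sigma^2);
#'   see [forecast_kt()].
#' @param jumpoff \code{"observed"} anchors on the last observed rates (the
#'   default), \code{"fitted"} on the last fitted rates.
#' @param ... unused.
#' @return Object of class \code{"lc_forecast"}: list with \code{kt}
#'   (a \code{"kt_forecast"}), \code{rates} (age-by-horizon matrix),
#'   \code{lower}, \code{upper}, \code{jumpoff_rates}, \code{years}
#'   (forecast calendar years), \code{ages}, \code{widths}.
#' @export
predict.lee_carter <- function(object, h = 10, order = c(0, 1, 0),
                               se_method = c("drift", "innovation"),
                               jumpoff = c("observed", "fitted"), ...) {
  se_method <- match.arg(se_method)
  jumpoff <- match.arg(jumpoff)
  n <- length(object$kt)
  model <- fit_kt_model(object$kt, order = order)
  kfc <- forecast_kt(model, horizon = h, se_method = se_method)
  jump <- if (jumpoff == "observed") object$surface$rates[, n]
          else exp(object$fitted_log[, n])
  rf <- forecast_rates(object$params, kfc, jump)
  rf$years <- max(object$surface$years) + seq_len(h)
  rf$ages <- object$surface$ages
  rf$widths <- object$surface$widths
  dimnames(rf$rates) <- dimnames(rf$lower) <- dimnames(rf$upper) <-
    list(age = as.character(rf$ages), year = as.character(rf$years))
  rf
}

#' @export
print.lc_forecast <- function(x, ...) {
  cat(sprintf("Lee-Carter rate forecast: %d age groups x %d years (%s-%s)\n",
              nrow(x$rates), ncol(x$rates),
              colnames(x$rates)[1], colnames(x$rates)[ncol(x$rates)]))
  cat(sprintf("  index: drift %.4f, innovation SD %.4f; se at h=%d: %.4f\n",
              x$kt$drift, x$kt$sigma, x$kt$horizon,
              x$kt$se_k[x$kt$horizon]))
  invisible(x)
}
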