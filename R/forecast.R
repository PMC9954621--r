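#' Fit a time-series model to the mortality index
#'
#' The default, and the classical Lee-Carter choice, is the random walk with
#' drift, ARIMA(0,1,0) plus constant: the drift is the mean of the first
#' differences of \code{k_t} and the innovation SD comes from the
#' first-difference residuals with denominator \code{n - 2} (one difference
#' lost, one degree of freedom for the drift). Any other \code{(p, d, q)}
#' order is delegated to [stats::arima()] behind the same contract, with a
#' drift regressor included when \code{d = 1}.
#'
#' @param k_t numeric vector, the fitted mortality index (length >= 4).
#' @param order ARIMA order; default \code{c(0, 1, 0)}.
#' @return Object of class \code{"kt_model"}: list with \code{k_t},
#'   \code{order}, \code{drift}, \code{sigma}, \code{n}, and (for non-default
#'   orders) the underlying \code{arima} fit.
#' @export
fit_kt_model <- function(k_t, order = c(0, 1, 0)) {
  k_t <- as.numeric(k_t)
  n <- length(k_t)
  if (n < 4) stop("fit_kt_model: need at least 4 index values")
  order <- as.integer(order)
  if (length(order) != 3L || any(order < 0))
    stop("fit_kt_model: order must be a non-negative (p, d, q) triple")
  if (all(order == c(0L, 1L, 0L))) {
    d <- diff(k_t)
    drift <- mean(d)
    resid <- d - drift
    sigma <- sqrt(sum(resid^2) / (n - 2))
    fit <- NULL
  } else {
    xreg <- if (order[2] == 1L) matrix(seq_len(n), ncol = 1,
                                       dimnames = list(NULL, "drift")) else NULL
    fit <- stats::arima(k_t, order = order, xreg = xreg,
                        include.mean = order[2] == 0L, method = "ML")
    drift <- if (!is.null(xreg)) unname(fit$coef["drift"]) else 0
    sigma <- sqrt(fit$sigma2)
  }
  structure(list(k_t = k_t, order = order, drift = drift, sigma = sigma,
                 n = n, arima_fit = fit),
            class = "kt_model")
}

#' @export
print.kt_model <- function(x, ...) {
  cat(sprintf("Mortality-index model ARIMA(%d,%d,%d)%s: drift %.4f, sigma %.4f (n = %d)\n",
              x$order[1], x$order[2], x$order[3],
              if (x$order[2] >= 1) "+drift" else "", x$drift, x$sigma, x$n))
  invisible(x)
}

#' Forecast the mortality index
#'
#' For the random walk with drift the point forecast is
#' \code{k_n + h * drift} and the forecast standard error is, by default,
#' \deqn{se_{k,h} = \sqrt{h\,\sigma^2 + h^2 \sigma^2 / (n - 1)},}
#' combining the accumulated innovation variance with the uncertainty of the
#' estimated drift (the drift is a mean of \code{n - 1} differences).
#' \code{se_method = "innovation"} drops the second term, giving the pure
#' random-walk \code{sqrt(h) * sigma}. Non-default ARIMA orders use
#' [stats::predict.Arima()].
#'
#' @param model a [fit_kt_model()] object.
#' @param horizon number of years ahead (>= 1).
#' @param se_method \code{"drift"} (default) or \code{"innovation"}.
#' @return Object of class \code{"kt_forecast"}: list with \code{horizon},
#'   \code{k_hat}, \code{se_k} (non-decreasing in h), \code{drift},
#'   \code{sigma}, \code{model_order}, \code{k_last} (the jump-off index
#'   value \code{k_n}).
#' @export
forecast_kt <- function(model, horizon, se_method = c("drift", "innovation")) {
  stopifnot(inherits(model, "kt_model"))
  se_method <- match.arg(se_method)
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("forecast_kt: horizon must be >= 1")
  n <- model$n
  k_last <- model$k_t[n]
  h <- seq_len(horizon)
  if (all(model$order == c(0L, 1L, 0L))) {
    k_hat <- k_last + h * model$drift
    se <- if (se_method == "drift")
      model$sigma * sqrt(h + h^2 / (n - 1)) else model$sigma * sqrt(h)
  } else {
    xreg <- if (model$order[2] == 1L)
      matrix(n + h, ncol = 1, dimnames = list(NULL, "drift")) else NULL
    pr <- stats::predict(model$arima_fit, n.ahead = horizon, newxreg = xreg)
    k_hat <- as.numeric(pr$pred); se <- as.numeric(pr$se)
  }
  structure(list(horizon = horizon, k_hat = k_hat, se_k = se,
                 drift = model$drift, sigma = model$sigma,
                 model_order = model$order, k_last = k_last),
            class = "kt_forecast")
}

#' Convert index forecasts to age-specific rate forecasts
#'
#' Applies the rate-projection identity anchored on the jump-off rates (the
#' most recent observed rates \code{m[x, n]}):
#' \deqn{\hat m_{x,n+h} = m_{x,n} \exp\{\hat b_x (\hat k_{n+h} - \hat k_n)\},}
#' with the approximate prediction interval
#' \eqn{\hat m_{x,n+h}\exp(\pm 2\,\hat b_x\,\mathrm{se}_{k,h})}. Only index
#' uncertainty enters the interval; errors in the age parameters are ignored,
#' as is conventional. The interval is exactly symmetric on the log scale;
#' bounds are ordered per cell so \code{lower <= rates <= upper} holds for
#' any sign of \code{b_x}.
#'
#' @param params fitted [lc_parameters()] (supplies \code{b_x}).
#' @param kfc a [forecast_kt()] object (supplies \code{k_hat}, \code{se_k}
#'   and the jump-off index value).
#' @param jumpoff positive vector of jump-off rates \code{m[x, n]}.
#' @return Object of class \code{"lc_forecast"}: list with \code{rates},
#'   \code{lower}, \code{upper} (age-by-horizon matrices),
#'   \code{jumpoff_rates} and \code{kt} (the index forecast).
#' @export
forecast_rates <- function(params, kfc, jumpoff) {
  stopifnot(inherits(params, "lc_parameters"), inherits(kfc, "kt_forecast"))
  jumpoff <- as.numeric(jumpoff)
  if (length(jumpoff) != length(params$b_x))
    stop("forecast_rates: jumpoff length must match the number of age groups")
  if (any(jumpoff <= 0))
    stop("forecast_rates data error: jump-off rates must be positive")
  dk <- kfc$k_hat - kfc$k_last
  point <- jumpoff * exp(outer(params$b_x, dk))
  spread <- exp(2 * outer(params$b_x, kfc$se_k))
  b1 <- point * spread; b2 <- point / spread
  structure(list(rates = point, lower = pmin(b1, b2), upper = pmax(b1, b2),
                 jumpoff_rates = jumpoff, kt = kfc,
                 ages = params$ages),
            class = "lc_forecast")
}
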