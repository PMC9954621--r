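#' Elementwise percent errors
#'
#' \code{(actual - predicted) / actual} per cell, so over-prediction yields a
#' negative error. Cells with zero actual value cannot be scaled and are
#' returned as \code{NA} with their count recorded in the
#' \code{"n_excluded"} attribute; downstream averages skip them.
#'
#' @param actual,predicted numeric vectors or matrices of the same shape.
#' @return Numeric array of the same shape; attribute \code{n_excluded}
#'   counts zero-actual cells.
#' @export
percent_errors <- function(actual, predicted) {
  if (!all(dim(as.matrix(actual)) == dim(as.matrix(predicted))))
    stop("percent_errors: actual and predicted shapes differ")
  a <- as.matrix(actual); p <- as.matrix(predicted)
  zero <- a == 0
  e <- (a - p) / a
  e[zero] <- NA_real_
  attr(e, "n_excluded") <- sum(zero)
  e
}

#' Mean absolute percent error
#'
#' \code{mean(|percent error|) * 100}, the MAPE on the percentage scale.
#' Scale-invariant: rescaling both inputs by a common factor leaves it
#' unchanged.
#'
#' @param actual,predicted numeric vectors or matrices of the same shape.
#' @return MAPE as a percentage (10 means 10\%).
#' @export
mape <- function(actual, predicted) {
  e <- percent_errors(actual, predicted)
  mean(abs(e), na.rm = TRUE) * 100
}

#' Forecast-error table by age and by year
#'
#' The two-axis error summary for a fitted or forecast rate surface:
#' \describe{
#'   \item{by_age}{per age group, the signed mean percent error (MPE) and the
#'     mean absolute percent error (MAPE) across years;}
#'   \item{by_year}{per year, the percent errors integrated (averaged) across
#'     ages — signed (IPE) and absolute (IAPE);}
#'   \item{overall}{the MAPE over all cells.}
#' }
#' IPE/IAPE here are the age-integrated analogues of MPE/MAPE: the per-year
#' average over the age-error profile, normalised by the number of ages.
#' Every measure is emitted both as a fraction (\code{*_frac}) and on the
#' x100 percentage scale (\code{*_pct}).
#'
#' @param actual a [mortality_surface()] or an age-by-year rate matrix.
#' @param predicted an \code{"lc_forecast"}, a fitted rate matrix, or a
#'   \code{"lee_carter"} fit (its within-sample fitted rates are used). Only
#'   overlapping years (by column name) are compared when both carry year
#'   labels; otherwise shapes must match.
#' @return Object of class \code{"lc_error_report"}: list with data frames
#'   \code{by_age} (age, mpe_frac, mpe_pct, mape_frac, mape_pct) and
#'   \code{by_year} (year, ipe_frac, ipe_pct, iape_frac, iape_pct), scalars
#'   \code{overall_mape_pct}, \code{overall_mape_frac}, and
#'   \code{n_excluded}.
#' @export
error_table <- function(actual, predicted) {
  am <- if (inherits(actual, "mortality_surface")) actual$rates else as.matrix(actual)
  pm <- if (inherits(predicted, "lc_forecast")) predicted$rates
        else if (inherits(predicted, "lee_carter")) exp(predicted$fitted_log)
        else as.matrix(predicted)
  ac <- colnames(am); pc <- colnames(pm)
  if (!is.null(ac) && !is.null(pc)) {
    common <- intersect(ac, pc)
    if (length(common) == 0L)
      stop("error_table: no overlapping years between actual and predicted")
    am <- am[, common, drop = FALSE]; pm <- pm[, common, drop = FALSE]
  } else if (!all(dim(am) == dim(pm)))
    stop("error_table: shapes differ and no year labels to align on")
  e <- percent_errors(am, pm)
  ages <- if (inherits(actual, "mortality_surface")) actual$ages
          else rownames(am) %||% seq_len(nrow(am))
  years <- colnames(am) %||% seq_len(ncol(am))
  mpe <- rowMeans(e, na.rm = TRUE)
  mape_a <- rowMeans(abs(e), na.rm = TRUE)
  ipe <- colMeans(e, na.rm = TRUE)
  iape <- colMeans(abs(e), na.rm = TRUE)
  structure(list(
    by_age = data.frame(age = ages, mpe_frac = mpe, mpe_pct = 100 * mpe,
                        mape_frac = mape_a, mape_pct = 100 * mape_a,
                        row.names = NULL),
    by_year = data.frame(year = years, ipe_frac = ipe, ipe_pct = 100 * ipe,
                         iape_frac = iape, iape_pct = 100 * iape,
                         row.names = NULL),
    overall_mape_frac = mean(abs(e), na.rm = TRUE),
    overall_mape_pct = 100 * mean(abs(e), na.rm = TRUE),
    n_excluded = attr(e, "n_excluded")),
    class = "lc_error_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lc_error_report <- function(x, digits = 5, ...) {
  cat(sprintf("Forecast/fit error report (overall MAPE %.4f%%, %d zero-actual cells excluded)\n",
              x$overall_mape_pct, x$n_excluded))
  cat("Averages across years, by age:\n")
  print(x$by_age[, c("age", "mpe_frac", "mape_frac")], digits = digits,
        row.names = FALSE)
  cat("Averages across ages, by year:\n")
  print(utils::head(x$by_year[, c("year", "ipe_frac", "iape_frac")], 10),
        digits = digits, row.names = FALSE)
  if (nrow(x$by_year) > 10) cat(sprintf("  ... %d more years\n", nrow(x$by_year) - 10))
  invisible(x)
}

#' Mean and variance of life-expectancy forecast errors
#'
#' Errors are signed, \code{actual - forecast}, in years; the variance is the
#' population variance (denominator \code{n}).
#'
#' @param actual_e0,forecast_e0 equal-length numeric vectors (length >= 2) of
#'   life expectancies over the test years.
#' @return List with \code{mean} and \code{variance}.
#' @export
life_expectancy_error_stats <- function(actual_e0, forecast_e0) {
  actual_e0 <- as.numeric(actual_e0); forecast_e0 <- as.numeric(forecast_e0)
  if (length(actual_e0) != length(forecast_e0))
    stop("life_expectancy_error_stats: lengths differ")
  if (length(actual_e0) < 2L)
    stop("life_expectancy_error_stats: need at least 2 years for a variance")
  err <- actual_e0 - forecast_e0
  list(mean = mean(err), variance = mean((err - mean(err))^2))
}

#' One-call forecast accuracy for a fitted model
#'
#' Convenience wrapper: forecasts over a held-out test surface's years and
#' returns the [error_table()] of forecast versus observed rates, plus the
#' life-expectancy error moments of the two rate schedules.
#'
#' @param fit a \code{"lee_carter"} model fitted on the training window.
#' @param test the held-out [mortality_surface()] (years following the
#'   training window).
#' @param ... passed to [predict.lee_carter()] (e.g. \code{se_method},
#'   \code{jumpoff}).
#' @param pad_to_birth passed to the life-table step.
#' @return List with \code{errors} (an \code{"lc_error_report"}),
#'   \code{e0_actual}, \code{e0_forecast} (per test year) and \code{le_stats}
#'   (mean/variance of their differences).
#' @export
lc_accuracy <- function(fit, test, ..., pad_to_birth = FALSE) {
  stopifnot(inherits(fit, "lee_carter"), inherits(test, "mortality_surface"))
  h <- length(test$years)
  if (min(test$years) != max(fit$surface$years) + 1L)
    stop("lc_accuracy: test years must start right after the training window")
  fc <- predict(fit, h = h, ...)
  errs <- error_table(test, fc)
  e0a <- life_expectancy_path(test$rates, widths = test$widths,
                              start_age = test$ages[1],
                              pad_to_birth = pad_to_birth)
  e0f <- life_expectancy_path(fc$rates, widths = test$widths,
                              start_age = test$ages[1],
                              pad_to_birth = pad_to_birth)
  list(errors = errs, e0_actual = e0a, e0_forecast = e0f,
       le_stats = life_expectancy_error_stats(e0a, e0f),
       forecast = fc)
}
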