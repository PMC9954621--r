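#' Pipeline configuration
#'
#' One flat key-value configuration for [run_pipeline()], with defaults
#' matching the package's headline protocol: train on 1990-2010, test on the
#' remaining observed years, forecast the index and rates through 2030.
#' Either a long-format surface CSV (\code{input}) or a simulation spec
#' (\code{sim}) supplies the data.
#'
#' @param input path to a long-format surface CSV ([read_surface_csv()]), or
#'   \code{NULL} to simulate.
#' @param sim an [sim_spec()] used when \code{input} is \code{NULL}; its seed
#'   is overridden by \code{seed}.
#' @param split_year last training year (default 2010).
#' @param forecast_end_year final forecast year (default 2030).
#' @param zero_floor rate floor for the log transform.
#' @param order index-model ARIMA order.
#' @param se_method,jumpoff forecast conventions, see [predict.lee_carter()].
#' @param pad_to_birth life-table padding mode, see [life_table()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing all randomness in the run.
#' @param quiet suppress progress lines.
#' @return A list of class \code{"lc_config"}.
#' @export
lc_config <- function(input = NULL, sim = sim_spec(), split_year = 2010,
                      forecast_end_year = 2030, zero_floor = 1e-8,
                      order = c(0, 1, 0),
                      se_method = c("drift", "innovation"),
                      jumpoff = c("observed", "fitted"),
                      pad_to_birth = FALSE, out_dir = tempfile("lcrun"),
                      seed = 42, quiet = FALSE) {
  se_method <- match.arg(se_method); jumpoff <- match.arg(jumpoff)
  if (split_year >= forecast_end_year)
    stop("lc_config: split_year must precede forecast_end_year")
  if (!is.null(input) && !file.exists(input))
    stop("lc_config: input file does not exist: ", input)
  structure(list(input = input, sim = sim, split_year = as.integer(split_year),
                 forecast_end_year = as.integer(forecast_end_year),
                 zero_floor = zero_floor, order = order,
                 se_method = se_method, jumpoff = jumpoff,
                 pad_to_birth = pad_to_birth, out_dir = out_dir,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "lc_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [lc_config()]; keys prefixed
#' \code{sim_} set fields of the simulation spec (e.g. \code{sim_n_ages},
#' \code{sim_kt_drift}).
#'
#' @param path YAML file.
#' @return An \code{"lc_config"}.
#' @export
read_lc_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_lc_config needs the 'yaml' package")
  y <- yaml::read_yaml(path)
  simkeys <- grep("^sim_", names(y), value = TRUE)
  simargs <- stats::setNames(y[simkeys], sub("^sim_", "", simkeys))
  y[simkeys] <- NULL
  if (length(simargs)) y$sim <- do.call(sim_spec, simargs)
  do.call(lc_config, y)
}

#' Run the full Lee-Carter pipeline
#'
#' Executes the complete protocol: load or simulate the surface, split into
#' training and test windows at \code{split_year}, fit the two-stage
#' Lee-Carter model on the training window, forecast the index and rates
#' through \code{forecast_end_year}, build life tables, and compute the
#' within-sample and out-of-sample error reports. Every stage's numeric
#' output is written as CSV under \code{out_dir}, plus a JSON run report; the
#' run is deterministic given the seed.
#'
#' @param config an [lc_config()] (or a YAML path accepted by
#'   [read_lc_config()]).
#' @return The run report, invisibly: a list of class \code{"lc_run_report"}
#'   with the fitted model, forecasts, error summaries, the \code{e_0}
#'   trajectory, file paths, and a provenance block (config echo, seed,
#'   package version, timestamp).
#' @export
run_pipeline <- function(config = lc_config()) {
  if (is.character(config)) config <- read_lc_config(config)
  stopifnot(inherits(config, "lc_config"))
  say <- function(stage, fmt, ...) if (!config$quiet)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  stage <- "load"
  report <- list(files = character(0))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE, quote = FALSE)
    report$files[[name]] <<- out(name)
  }
  tryCatch({
    surface <- if (!is.null(config$input)) read_surface_csv(config$input)
    else {
      spec <- config$sim; spec$seed <- config$seed
      simulate_surface(spec)
    }
    write_surface_csv(surface, out("surface.csv"))
    report$files[["surface.csv"]] <- out("surface.csv")
    say(stage, "surface %dx%d (%s)", nrow(surface$rates), ncol(surface$rates),
        surface$label)

    stage <- "split"
    sp <- split_train_test(surface, config$split_year)

    stage <- "fit"
    fit <- lee_carter(sp$train, zero_floor = config$zero_floor)
    say(stage, "PV %.2f%%, k_t %.3f -> %.3f", 100 * fit$percent_variation,
        fit$kt[1], fit$kt[length(fit$kt)])
    emit(data.frame(component = rep(c("a_x", "b_x"), each = length(fit$ax)),
                    label = c(fit$surface$ages, fit$surface$ages),
                    value = c(fit$ax, fit$bx)), "parameters_age.csv")
    emit(data.frame(component = "k_t", label = fit$surface$years,
                    value = fit$kt), "parameters_kt.csv")
    emit(data.frame(age = rep(fit$surface$ages, ncol(fit$residuals)),
                    year = rep(fit$surface$years, each = nrow(fit$residuals)),
                    fitted_log = as.vector(fit$fitted_log),
                    residual = as.vector(fit$residuals)), "diagnostics.csv")

    stage <- "forecast"
    h <- config$forecast_end_year - config$split_year
    fc <- predict(fit, h = h, order = config$order,
                  se_method = config$se_method, jumpoff = config$jumpoff)
    say(stage, "index to %d: %.3f (se %.3f)", config$forecast_end_year,
        fc$kt$k_hat[h], fc$kt$se_k[h])
    emit(data.frame(year = fc$years, k_hat = fc$kt$k_hat, se_k = fc$kt$se_k),
         "kt_forecast.csv")
    emit(data.frame(age = rep(fc$ages, ncol(fc$rates)),
                    year = rep(fc$years, each = nrow(fc$rates)),
                    point = as.vector(fc$rates),
                    lower = as.vector(fc$lower),
                    upper = as.vector(fc$upper)), "rate_forecast.csv")

    stage <- "lifetable"
    e0_forecast <- life_expectancy_path(fc$rates, widths = fc$widths,
                                        start_age = fc$ages[1],
                                        pad_to_birth = config$pad_to_birth)
    lt_last <- life_table(fc$rates[, h], widths = fc$widths,
                          start_age = fc$ages[1],
                          pad_to_birth = config$pad_to_birth)
    emit(cbind(year = config$forecast_end_year, lt_last),
         "life_table_final_year.csv")
    emit(data.frame(year = fc$years, e0 = unname(e0_forecast)),
         "e0_trajectory.csv")

    stage <- "evaluate"
    within <- error_table(sp$train, fit)
    acc <- lc_accuracy(fit, sp$test, order = config$order,
                       se_method = config$se_method, jumpoff = config$jumpoff,
                       pad_to_birth = config$pad_to_birth)
    say(stage, "within MAPE %.4f%%, out-of-sample MAPE %.4f%%",
        within$overall_mape_pct, acc$errors$overall_mape_pct)
    emit(acc$errors$by_age, "errors_by_age.csv")
    emit(acc$errors$by_year, "errors_by_year.csv")
    emit(data.frame(
      measure = c("within_mape_pct", "oos_mape_pct", "le_error_mean",
                  "le_error_variance", "percent_variation"),
      value = c(within$overall_mape_pct, acc$errors$overall_mape_pct,
                acc$le_stats$mean, acc$le_stats$variance,
                fit$percent_variation)), "summary.csv")

    report <- c(report, list(
      fit = fit, forecast = fc, within = within, accuracy = acc,
      e0_trajectory = e0_forecast,
      percent_variation = fit$percent_variation,
      constraint_residuals = c(b = sum(fit$bx) - 1, k = sum(fit$kt)),
      provenance = list(config = unclass(config)[setdiff(names(config), "sim")],
                        sim = if (is.null(config$input)) unclass(config$sim),
                        seed = config$seed,
                        package_version = as.character(utils::packageVersion("lcmort")),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))))
    prov <- report$provenance
    jsonlite::write_json(
      list(seed = prov$seed, package_version = prov$package_version,
           percent_variation = fit$percent_variation,
           within_mape_pct = within$overall_mape_pct,
           oos_mape_pct = acc$errors$overall_mape_pct,
           le_error_mean = acc$le_stats$mean,
           le_error_variance = acc$le_stats$variance,
           files = names(report$files)),
      out("report.json"), auto_unbox = TRUE, digits = NA)
    report$files[["report.json"]] <- out("report.json")
    class(report) <- "lc_run_report"
    invisible(report)
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.lc_run_report <- function(x, ...) {
  cat("Lee-Carter pipeline run\n")
  cat(sprintf("  PV %.2f%%; within MAPE %.4f%%; out-of-sample MAPE %.4f%%\n",
              100 * x$percent_variation, x$within$overall_mape_pct,
              x$accuracy$errors$overall_mape_pct))
  cat(sprintf("  life-expectancy error: mean %.4f, variance %.6f years\n",
              x$accuracy$le_stats$mean, x$accuracy$le_stats$variance))
  cat(sprintf("  %d artifact files under %s\n", length(x$files),
              dirname(x$files[[1]])))
  invisible(x)
}
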