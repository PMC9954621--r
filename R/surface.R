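#' Construct a mortality surface
#'
#' A mortality surface is an age-by-year grid of death counts, person-years of
#' exposure and central death rates for one population. Rows are age groups
#' (closed bands \code{[x, x + width)}, the last band may be open-ended),
#' columns are consecutive calendar years. Rates are stored per person-year;
#' scaling to per-100,000 happens only at presentation.
#'
#' At least two of \code{deaths}, \code{exposures}, \code{rates} must be
#' derivable: supply \code{deaths} and \code{exposures} (rates are computed as
#' their elementwise ratio), or \code{rates} and \code{exposures} (deaths are
#' back-computed), or all three (checked for consistency).
#'
#' @param ages numeric vector of age-group lower bounds, strictly increasing.
#' @param years integer vector of calendar years, consecutive.
#' @param deaths,exposures,rates age-by-year numeric matrices. Exposures must
#'   be strictly positive, deaths and rates non-negative.
#' @param widths age-interval widths in years; default 5 for every band.
#' @param label free-text population tag carried through the analysis.
#' @return An object of class \code{"mortality_surface"}: a list with fields
#'   \code{ages}, \code{widths}, \code{years}, \code{deaths}, \code{exposures},
#'   \code{rates}, \code{label}.
#' @examples
#' s <- mortality_surface(ages = c(50, 55), years = 2000:2002,
#'                        deaths = matrix(c(10, 20, 12, 22, 14, 24), 2, 3),
#'                        exposures = matrix(1e5, 2, 3))
#' s$rates[, 1]
#' @export
mortality_surface <- function(ages, years, deaths = NULL, exposures = NULL,
                              rates = NULL, widths = NULL, label = "") {
  ages <- as.numeric(ages)
  years <- as.integer(years)
  if (length(ages) < 1L || length(years) < 1L)
    stop("mortality_surface: need at least one age group and one year")
  if (is.unsorted(ages, strictly = TRUE))
    stop("mortality_surface: age-group lower bounds must be strictly increasing")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("mortality_surface: years must be consecutive calendar years")
  if (is.null(widths)) widths <- rep(5, length(ages))
  widths <- as.numeric(widths)
  if (length(widths) != length(ages) || any(widths <= 0))
    stop("mortality_surface: widths must be positive, one per age group")
  if (any(diff(ages) < widths[-length(widths)]))
    stop("mortality_surface: age groups overlap")

  r <- length(ages); n <- length(years)
  chk <- function(m, nm, allow_zero = TRUE) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == c(r, n)))
      stop(sprintf("mortality_surface: %s must be %d x %d", nm, r, n))
    if (!all(is.finite(m))) stop(sprintf("mortality_surface: %s has non-finite cells", nm))
    if (allow_zero && any(m < 0)) stop(sprintf("mortality_surface: %s has negative cells", nm))
    if (!allow_zero && any(m <= 0)) stop(sprintf("mortality_surface: %s must be strictly positive", nm))
    dimnames(m) <- list(age = as.character(ages), year = as.character(years))
    m
  }
  deaths <- chk(deaths, "deaths"); rates <- chk(rates, "rates")
  exposures <- chk(exposures, "exposures", allow_zero = FALSE)

  if (is.null(exposures))
    stop("mortality_surface: exposures are required (use exposures = 1 grid if only rates are known)")
  if (is.null(deaths) && is.null(rates))
    stop("mortality_surface: supply deaths or rates")
  if (is.null(deaths)) {
    deaths <- rates * exposures
    dimnames(deaths) <- dimnames(exposures)
  }
  computed <- deaths / exposures
  if (!is.null(rates)) {
    rel <- abs(computed - rates) / pmax(abs(rates), 1e-300)
    if (any(rel[rates > 0] > 1e-12) || any(computed[rates == 0] != 0))
      stop("mortality_surface: rates are inconsistent with deaths/exposures")
  }
  rates <- computed
  structure(list(ages = ages, widths = widths, years = years,
                 deaths = deaths, exposures = exposures, rates = rates,
                 label = as.character(label)[1]),
            class = "mortality_surface")
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat(sprintf("Mortality surface%s: %d age groups (%g-%g) x %d years (%d-%d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$ages), min(x$ages), max(x$ages) + x$widths[length(x$widths)],
              length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  total deaths %.1f, rate range [%.3g, %.3g] per person-year\n",
              sum(x$deaths), min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
dim.mortality_surface <- function(x) c(length(x$ages), length(x$years))

#' Log-transform a mortality surface
#'
#' Computes \code{ln(m[x, t])}, the input to Lee-Carter estimation. Cells whose
#' rate falls below \code{zero_floor} (in particular exact zeros, whose log is
#' undefined) are floored at \code{zero_floor} and flagged in \code{zero_mask},
#' so the matrix stays finite and complete for the singular value
#' decomposition.
#'
#' @param surface a \code{mortality_surface}.
#' @param zero_floor positive rate (per person-year) used as the floor;
#'   default \code{1e-8}.
#' @return Object of class \code{"log_surface"}: list with \code{values}
#'   (age-by-year matrix of floored log-rates), \code{zero_mask} (logical
#'   matrix, \code{TRUE} where the floor was imposed), plus the \code{ages},
#'   \code{widths} and \code{years} labels.
#' @export
to_log_surface <- function(surface, zero_floor = 1e-8) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (!is.numeric(zero_floor) || length(zero_floor) != 1L || zero_floor <= 0)
    stop("to_log_surface: zero_floor must be a positive scalar")
  r <- surface$rates
  if (any(r < 0)) stop("to_log_surface: negative rates")
  mask <- r < zero_floor
  v <- log(pmax(r, zero_floor))
  dimnames(v) <- dimnames(r); dimnames(mask) <- dimnames(r)
  structure(list(values = v, zero_mask = mask, ages = surface$ages,
                 widths = surface$widths, years = surface$years),
            class = "log_surface")
}

#' Split a surface into training and test windows
#'
#' Partitions the surface by calendar year into a training window ending at
#' \code{split_year} (inclusive) and a test window of all later years, the
#' usual setup for out-of-sample forecast evaluation (e.g. train 1990-2010,
#' test 2011-2019).
#'
#' @param surface a \code{mortality_surface}.
#' @param split_year last year kept in the training window; must be strictly
#'   inside the surface's year range.
#' @return List of class \code{"split_surfaces"} with elements \code{train},
#'   \code{test} (both \code{mortality_surface}) and \code{split_year}.
#' @export
split_train_test <- function(surface, split_year) {
  stopifnot(inherits(surface, "mortality_surface"))
  split_year <- as.integer(split_year)
  yrs <- surface$years
  if (split_year < min(yrs) || split_year >= max(yrs))
    stop("split_train_test: split_year must lie strictly inside the year range")
  take <- function(idx) mortality_surface(
    ages = surface$ages, years = yrs[idx],
    deaths = surface$deaths[, idx, drop = FALSE],
    exposures = surface$exposures[, idx, drop = FALSE],
    widths = surface$widths, label = surface$label)
  idx <- yrs <= split_year
  structure(list(train = take(idx), test = take(!idx), split_year = split_year),
            class = "split_surfaces")
}

#' Write a surface to long-format CSV
#'
#' One row per (age, year) cell with columns \code{age}, \code{width},
#' \code{year}, \code{deaths}, \code{exposure}; rows ordered by age then year
#' so output is bit-stable. Full double precision is preserved.
#'
#' @param surface a \code{mortality_surface}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_surface_csv()]
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "mortality_surface"))
  r <- length(surface$ages); n <- length(surface$years)
  df <- data.frame(
    age = rep(surface$ages, each = n),
    width = rep(surface$widths, each = n),
    year = rep(surface$years, times = r),
    deaths = sprintf("%.17g", as.vector(t(surface$deaths))),
    exposure = sprintf("%.17g", as.vector(t(surface$exposures))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format surface CSV
#'
#' Counterpart of [write_surface_csv()]. Requires columns \code{age},
#' \code{year}, \code{deaths}, \code{exposure} and optionally \code{width};
#' every (age, year) cell of the rectangle must be present exactly once.
#'
#' @param path input file path.
#' @param label population tag for the returned surface.
#' @return A \code{mortality_surface}.
#' @export
read_surface_csv <- function(path, label = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("age", "year", "deaths", "exposure")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_surface_csv: missing required column(s): ", paste(miss, collapse = ", "))
  ages <- sort(unique(df$age)); years <- sort(unique(df$year))
  widths <- NULL
  if ("width" %in% names(df))
    widths <- vapply(ages, function(a) unique(df$width[df$age == a])[1], numeric(1))
  pv <- .pivot_cells(df$age, df$year, ages, years,
                     deaths = df$deaths, exposure = df$exposure)
  mortality_surface(ages = ages, years = years, deaths = pv$deaths,
                    exposures = pv$exposure, widths = widths, label = label)
}

# Pivot long (age, year, value...) records to complete age x year matrices.
# Errors on duplicate or missing cells; years must be contiguous.
.pivot_cells <- function(age, year, ages, years, ...) {
  vals <- list(...)
  if (length(years) > 1L && any(diff(sort(years)) != 1))
    stop("surface data error: years are not contiguous")
  r <- length(ages); n <- length(years)
  i <- match(age, ages); j <- match(year, years)
  key <- (i - 1L) * n + j
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("surface data error: duplicate cell (age %s, year %s)",
                 age[d], year[d]))
  }
  if (length(key) < r * n) {
    have <- logical(r * n); have[key] <- TRUE
    m <- which(!have)[1]
    stop(sprintf("surface data error: missing cell (age %s, year %s)",
                 ages[(m - 1L) %/% n + 1L], years[(m - 1L) %% n + 1L]))
  }
  lapply(vals, function(v) {
    mat <- matrix(NA_real_, r, n)
    mat[cbind(i, j)] <- v
    mat
  })
}

#' Read a GBD results-tool CSV export
#'
#' Reads the delimited export dialect of the Global Burden of Disease results
#' tool (one row per measure/location/sex/age/cause/metric/year) and pivots it
#' to an age-by-year [mortality_surface()]. Two paths are supported, because
#' such exports carry either death rates or death counts:
#' \describe{
#'   \item{\code{metric = "Rate"}}{\code{val} is a death rate per
#'     \code{rate_scale} persons (GBD prints per 100,000). Exposures are set
#'     to \code{rate_scale} person-years per cell so that deaths/exposure
#'     reproduces the rate; absolute counts are then nominal.}
#'   \item{\code{metric = "Deaths"}}{\code{val} is a death count; a companion
#'     data frame or CSV of population (\code{population}) in the same dialect
#'     supplies exposures.}
#' }
#' Age-group labels like \code{"50 to 54"} or \code{"50-54 years"} are parsed
#' to lower bounds and widths; the open-ended \code{"85 plus"}/\code{"95+"}
#' style is accepted. Upper/lower uncertainty columns are ignored.
#'
#' @param path CSV file path (or a data frame already read).
#' @param metric which metric rows to keep: \code{"Rate"} or \code{"Deaths"}.
#' @param age_range optional length-2 numeric, keep age groups whose lower
#'   bound lies in \code{[age_range[1], age_range[2]]}.
#' @param years optional integer vector of years to keep.
#' @param population for \code{metric = "Deaths"}: a CSV path or data frame in
#'   the same dialect whose \code{val} column is population.
#' @param rate_scale persons in the denominator of the published rate
#'   (default \code{1e5}).
#' @param columns named character vector mapping the dialect's column roles
#'   (\code{age}, \code{year}, \code{metric}, \code{val}) to the file's column
#'   names; defaults match the results-tool export.
#' @param label population tag; defaults to the file's location value.
#' @return A \code{mortality_surface}.
#' @export
read_gbd_csv <- function(path, metric = c("Rate", "Deaths"), age_range = NULL,
                         years = NULL, population = NULL, rate_scale = 1e5,
                         columns = c(age = "age", year = "year",
                                     metric = "metric", val = "val"),
                         label = NULL) {
  metric <- match.arg(metric)
  df <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  cols <- c(age = "age", year = "year", metric = "metric", val = "val")
  cols[names(columns)] <- columns
  miss <- setdiff(unname(cols), names(df))
  if (length(miss))
    stop("read_gbd_csv configuration error: column(s) not in file: ",
         paste(miss, collapse = ", "))
  keep <- df[tolower(df[[cols["metric"]]]) == tolower(metric), , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("read_gbd_csv: no rows with metric '", metric, "'")
  ag <- .parse_gbd_age(keep[[cols["age"]]])
  yr <- as.integer(keep[[cols["year"]]])
  sel <- rep(TRUE, nrow(keep))
  if (!is.null(age_range)) sel <- sel & ag$lower >= age_range[1] & ag$lower <= age_range[2]
  if (!is.null(years)) sel <- sel & yr %in% as.integer(years)
  keep <- keep[sel, , drop = FALSE]; ag <- lapply(ag, `[`, sel); yr <- yr[sel]
  if (nrow(keep) == 0L) stop("read_gbd_csv: no rows left after age/year selection")
  ages <- sort(unique(ag$lower)); yrs <- sort(unique(yr))
  widths <- vapply(ages, function(a) ag$width[ag$lower == a][1], numeric(1))
  pv <- .pivot_cells(ag$lower, yr, ages, yrs, val = as.numeric(keep[[cols["val"]]]))
  if (is.null(label)) {
    loc <- intersect(c("location", "location_name"), names(df))
    label <- if (length(loc)) as.character(keep[[loc[1]]][1]) else ""
  }
  if (metric == "Rate") {
    exposures <- matrix(rate_scale, length(ages), length(yrs))
    deaths <- pv$val / rate_scale * exposures
    return(mortality_surface(ages, yrs, deaths = deaths, exposures = exposures,
                             widths = widths, label = label))
  }
  if (is.null(population))
    stop("read_gbd_csv configuration error: metric 'Deaths' needs a population table")
  pop <- if (is.data.frame(population)) population
         else utils::read.csv(population, check.names = FALSE)
  pag <- .parse_gbd_age(pop[[cols["age"]]])
  psel <- pag$lower %in% ages & as.integer(pop[[cols["year"]]]) %in% yrs
  pop <- pop[psel, , drop = FALSE]; pag <- lapply(pag, `[`, psel)
  pe <- .pivot_cells(pag$lower, as.integer(pop[[cols["year"]]]), ages, yrs,
                     val = as.numeric(pop[[cols["val"]]]))
  mortality_surface(ages, yrs, deaths = pv$val, exposures = pe$val,
                    widths = widths, label = label)
}

# Parse GBD-style age labels ("50 to 54", "50-54 years", "85 plus", "95+",
# "25") into lower bound and width. Open-ended groups get width 5 by
# convention; the life-table layer treats the final group as open regardless.
.parse_gbd_age <- function(x) {
  x <- trimws(gsub("years?", "", tolower(as.character(x))))
  lower <- width <- numeric(length(x))
  for (ii in seq_along(x)) {
    s <- x[ii]
    if (grepl("plus|\\+", s)) {
      lo <- as.numeric(sub("^([0-9]+).*", "\\1", s)); w <- 5
    } else if (grepl("to|-", s)) {
      parts <- as.numeric(strsplit(s, "to|-")[[1]])
      lo <- parts[1]; w <- parts[2] - parts[1] + 1
    } else {
      lo <- as.numeric(s); w <- 1
    }
    if (is.na(lo)) stop("read_gbd_csv data error: unparseable age label '", x[ii], "'")
    lower[ii] <- lo; width[ii] <- w
  }
  list(lower = lower, width = width)
}
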