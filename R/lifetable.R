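#' Abridged life table by Chiang's method
#'
#' Converts an age schedule of central death rates \code{m_x} into a full
#' abridged life table and life expectancy. For closed intervals of width
#' \code{n} the death probability is
#' \deqn{q_x = \frac{n\,m_x}{1 + n\,(1 - a_x)\,m_x},}
#' capped at 1, where \code{a_x} is Chiang's fraction of the interval lived
#' by those dying in it (default 0.5). The final interval is open-ended:
#' \code{q = 1} and \code{L = l / m} (constant-hazard closure), so its rate
#' must be positive. Survivorship starts from the radix
#' \code{l_0 = 100,000}; person-years are
#' \code{L_x = n (l_x - (1 - a_x) d_x)}, \code{T_x} accumulates \code{L}
#' from the bottom up, and \code{e_x = T_x / l_x}.
#'
#' When the schedule is cause-specific (e.g. breast-cancer rates only), the
#' resulting \code{e_x} is a summary index of that schedule, not an all-cause
#' life expectancy; interpret accordingly.
#'
#' @param rates central death rates per person-year, one per age group.
#' @param widths interval widths in years (the last is the open interval's
#'   nominal width, used only for labelling).
#' @param start_age age at the start of the first interval.
#' @param a_fraction Chiang's a, scalar or per-group vector; default 0.5.
#' @param radix starting cohort size, default 100,000.
#' @param pad_to_birth if \code{TRUE}, prepend zero-mortality years from age 0
#'   to \code{start_age} so the table truly starts at birth (everyone survives
#'   to the first supplied group); "life expectancy at birth" then includes
#'   those \code{start_age} guaranteed years. Default \code{FALSE}: the table
#'   starts at the first supplied group.
#' @return A \code{data.frame} of class \code{"life_table"} with columns
#'   \code{x}, \code{n}, \code{m_x}, \code{q_x}, \code{l_x}, \code{d_x},
#'   \code{L_x}, \code{T_x}, \code{e_x}.
#' @examples
#' lt <- life_table(c(0.002, 0.005, 0.02, 0.5), widths = c(5, 5, 5, 5),
#'                  start_age = 70)
#' life_expectancy(lt)
#' @export
life_table <- function(rates, widths = rep(5, length(rates)),
                       start_age = 0, a_fraction = 0.5, radix = 1e5,
                       pad_to_birth = FALSE) {
  rates <- as.numeric(rates)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("life_table: rates must be finite and non-negative")
  ng <- length(rates)
  if (ng < 1L) stop("life_table: empty schedule")
  widths <- rep_len(as.numeric(widths), ng)
  if (any(widths <= 0)) stop("life_table: widths must be positive")
  a <- rep_len(as.numeric(a_fraction), ng)
  if (any(a < 0) || any(a > 1)) stop("life_table: a_fraction must lie in [0, 1]")
  if (rates[ng] <= 0)
    stop("life_table table error: zero rate in the open-ended final interval")
  if (pad_to_birth && start_age > 0) {
    k <- start_age  # one-year zero-mortality intervals down to age 0
    rates <- c(rep(0, k), rates)
    widths <- c(rep(1, k), widths)
    a <- c(rep(0.5, k), a)
    ng <- ng + k
    start_age <- 0
  }
  x <- start_age + c(0, cumsum(widths))[seq_len(ng)]
  q <- widths * rates / (1 + widths * (1 - a) * rates)
  q <- pmin(q, 1)
  q[ng] <- 1
  l <- numeric(ng); l[1] <- radix
  for (i in seq_len(ng - 1L)) l[i + 1] <- l[i] * (1 - q[i])
  d <- l * q
  L <- widths * (l - (1 - a) * d)
  L[ng] <- if (l[ng] > 0) l[ng] / rates[ng] else 0
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)
  structure(data.frame(x = x, n = widths, m_x = rates, q_x = q, l_x = l,
                       d_x = d, L_x = L, T_x = T, e_x = e),
            class = c("life_table", "data.frame"))
}

#' Life expectancy at the first age of a life table
#'
#' Extracts \code{e_x = T_x / l_x} at the table's first interval — life
#' expectancy at birth when the table starts at (or was padded to) age 0.
#'
#' @param table a [life_table()].
#' @return A single number of years.
#' @export
life_expectancy <- function(table) {
  stopifnot(inherits(table, "life_table"))
  table$e_x[1]
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Abridged life table (Chiang), %d age groups, radix %g\n",
              nrow(x), x$l_x[1]))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Life-expectancy trajectory from a rate-forecast matrix
#'
#' Builds one Chiang life table per column of an age-by-year rate matrix and
#' returns the life expectancies, e.g. the projected \code{e_0} path over a
#' forecast horizon.
#'
#' @param rates age-by-year matrix of central death rates.
#' @param widths,start_age,a_fraction,radix,pad_to_birth as in [life_table()].
#' @return Named numeric vector, one life expectancy per column.
#' @export
life_expectancy_path <- function(rates, widths = rep(5, nrow(rates)),
                                 start_age = 0, a_fraction = 0.5,
                                 radix = 1e5, pad_to_birth = FALSE) {
  rates <- as.matrix(rates)
  out <- vapply(seq_len(ncol(rates)), function(j)
    life_expectancy(life_table(rates[, j], widths = widths,
                               start_age = start_age, a_fraction = a_fraction,
                               radix = radix, pad_to_birth = pad_to_birth)),
    numeric(1))
  names(out) <- colnames(rates)
  out
}
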