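#' Specify a synthetic mortality surface
#'
#' Describes the generative model used to build test surfaces with the
#' structure the Lee-Carter analysis assumes: log-rates
#' \code{ln mu[x, t] = a[x] + b[x] * k[t]} with a mortality index \code{k}
#' following a random walk with drift, and death counts drawn around
#' \code{exposure * mu} under the chosen noise model.
#'
#' The defaults emulate a screen-age/late-onset female breast-cancer stratum:
#' seven 5-year age bands from 50 to 84, thirty annual periods (1990-2019),
#' log-rates rising smoothly with age from roughly 2 to 12 per 100,000, an
#' index drifting by -0.5 per year, and one million person-years of exposure
#' per cell. See [sim_spec_early_onset()] for the noisier young-age analogue.
#'
#' @param n_ages,n_years grid dimensions.
#' @param a_profile true \code{a[x]}, mean log-rate by age (length
#'   \code{n_ages}).
#' @param b_profile true age sensitivities \code{b[x]}; normalised to sum to 1.
#' @param kt_drift per-year drift of the true index.
#' @param kt_sigma innovation SD of the index random walk (0 gives an exactly
#'   linear index).
#' @param exposure_level person-years at risk per cell.
#' @param noise_model \code{"poisson"} (default), \code{"negative_binomial"},
#'   or \code{"none"} (deaths set exactly to their expectation).
#' @param nb_dispersion negative-binomial size parameter; variance is
#'   \code{mu * (1 + mu / nb_dispersion)}.
#' @param first_age,first_year,age_width labelling of the grid.
#' @param seed integer seed making the surface reproducible.
#' @param label population tag.
#' @return Object of class \code{"lc_sim_spec"}.
#' @export
sim_spec <- function(n_ages = 7, n_years = 30,
                     a_profile = log(seq(2e-5, 1.2e-4, length.out = n_ages)),
                     b_profile = rep(1 / n_ages, n_ages),
                     kt_drift = -0.5, kt_sigma = 0.3,
                     exposure_level = 1e6,
                     noise_model = c("poisson", "negative_binomial", "none"),
                     nb_dispersion = 50,
                     first_age = 50, first_year = 1990, age_width = 5,
                     seed = 1, label = "synthetic") {
  noise_model <- match.arg(noise_model)
  n_ages <- as.integer(n_ages); n_years <- as.integer(n_years)
  if (length(a_profile) != n_ages || length(b_profile) != n_ages)
    stop("sim_spec: a_profile and b_profile must have length n_ages")
  if (abs(sum(b_profile)) < 1e-12)
    stop("sim_spec: b_profile sums to zero and cannot be normalised")
  b_profile <- b_profile / sum(b_profile)
  if (kt_sigma < 0 || exposure_level <= 0 || nb_dispersion <= 0)
    stop("sim_spec: kt_sigma must be >= 0, exposure_level and nb_dispersion > 0")
  structure(list(n_ages = n_ages, n_years = n_years,
                 a_profile = as.numeric(a_profile),
                 b_profile = as.numeric(b_profile),
                 kt_drift = kt_drift, kt_sigma = kt_sigma,
                 exposure_level = exposure_level, noise_model = noise_model,
                 nb_dispersion = nb_dispersion,
                 first_age = first_age, first_year = first_year,
                 age_width = age_width, seed = as.integer(seed),
                 label = label),
            class = "lc_sim_spec")
}

#' Early-onset stratum preset
#'
#' Five 5-year bands from 25 to 49 with low death rates (about 0.5 to 4 per
#' 100,000), giving small Poisson counts and hence the irregular log-rate
#' surface characteristic of early-onset cause-specific mortality. The
#' screen-age preset [sim_spec()] produces 10-40x larger counts at the same
#' exposure, so its log-surface is much smoother — the contrast used to study
#' how forecast accuracy depends on stratum smoothness.
#'
#' @param ... overrides passed on to [sim_spec()].
#' @return An \code{"lc_sim_spec"}.
#' @export
sim_spec_early_onset <- function(...) {
  args <- list(n_ages = 5, n_years = 30,
               a_profile = log(seq(5e-6, 4e-5, length.out = 5)),
               b_profile = rep(1 / 5, 5),
               kt_drift = -0.5, kt_sigma = 0.3,
               first_age = 25, label = "synthetic early-onset")
  args[names(list(...))] <- list(...)
  do.call(sim_spec, args)
}

#' Screen-age/late-onset stratum preset
#'
#' Alias for [sim_spec()] defaults with an explicit label.
#' @param ... overrides passed on to [sim_spec()].
#' @return An \code{"lc_sim_spec"}.
#' @export
sim_spec_screen_age <- function(...) {
  args <- list(label = "synthetic screen-age/late-onset")
  args[names(list(...))] <- list(...)
  do.call(sim_spec, args)
}

# Run code under a spec-derived RNG state without disturbing the caller's.
.with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate true Lee-Carter parameters from a simulation spec
#'
#' Builds the true \code{(a, b, k)} triple: \code{a} and \code{b} are copied
#' from the spec, and \code{k} is a seeded random walk with drift
#' \code{kt_drift} and innovation SD \code{kt_sigma}, centred so that
#' \code{sum(k) = 0}. With \code{kt_sigma = 0} the index is the centred
#' arithmetic sequence with common difference \code{kt_drift}.
#'
#' @param spec an [sim_spec()] object.
#' @return An \code{"lc_parameters"} object (see [lc_parameters()]) with empty
#'   \code{singular_values} (true parameters are not an SVD product).
#' @export
generate_true_parameters <- function(spec) {
  stopifnot(inherits(spec, "lc_sim_spec"))
  steps <- .with_sim_seed(spec$seed, 0L,
    spec$kt_drift + spec$kt_sigma * stats::rnorm(spec$n_years - 1L))
  k <- cumsum(c(0, steps))
  k <- k - mean(k)
  lc_parameters(a_x = spec$a_profile, b_x = spec$b_profile, k_t = k,
                ages = spec$first_age + spec$age_width * (seq_len(spec$n_ages) - 1L),
                years = spec$first_year + seq_len(spec$n_years) - 1L)
}

#' Simulate a mortality surface
#'
#' Builds true rates \code{mu[x, t] = exp(a[x] + b[x] * k[t])}, multiplies by
#' the exposure level, and draws death counts under the spec's noise model:
#' exactly \code{exposure * mu} (\code{"none"}), Poisson with that mean, or
#' negative binomial with that mean and variance
#' \code{mu_N * (1 + mu_N / nb_dispersion)}.
#'
#' @param spec an [sim_spec()] object.
#' @param params optional \code{"lc_parameters"}; defaults to
#'   [generate_true_parameters()] of the spec.
#' @return A [mortality_surface()] whose \code{label} comes from the spec.
#' @export
simulate_surface <- function(spec, params = generate_true_parameters(spec)) {
  stopifnot(inherits(spec, "lc_sim_spec"), inherits(params, "lc_parameters"))
  if (length(params$a_x) != spec$n_ages || length(params$k_t) != spec$n_years)
    stop("simulate_surface: params dimensions do not match spec")
  eta <- outer(params$a_x, rep(1, spec$n_years)) + outer(params$b_x, params$k_t)
  if (any(eta > 700)) {
    bad <- which(eta > 700, arr.ind = TRUE)[1, ]
    stop(sprintf("simulate_surface data error: exp overflow at cell (age %d, year %d)",
                 bad[1], bad[2]))
  }
  mu <- exp(eta)
  lam <- spec$exposure_level * mu
  ncell <- length(lam)
  deaths <- switch(spec$noise_model,
    none = lam,
    poisson = .with_sim_seed(spec$seed, 1L, stats::rpois(ncell, lam)),
    negative_binomial = .with_sim_seed(spec$seed, 1L,
      stats::rnbinom(ncell, size = spec$nb_dispersion, mu = lam)))
  deaths <- matrix(as.numeric(deaths), spec$n_ages, spec$n_years)
  mortality_surface(
    ages = spec$first_age + spec$age_width * (seq_len(spec$n_ages) - 1L),
    years = spec$first_year + seq_len(spec$n_years) - 1L,
    deaths = deaths,
    exposures = matrix(spec$exposure_level, spec$n_ages, spec$n_years),
    widths = rep(spec$age_width, spec$n_ages),
    label = spec$label)
}
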