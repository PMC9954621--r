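---
title: "Modelling cause-specific mortality with lcmort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cause-specific mortality with lcmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmort)
```

## The model

`lcmort` fits the Lee–Carter log-bilinear model to an age-by-year surface of
central death rates $m_{x,t}$ (deaths per person-year in age group $x$,
calendar year $t$):

$$\ln m_{x,t} = a_x + b_x k_t + e_{x,t},$$

where $a_x$ is the mean log-rate of age group $x$ over the observation
window, $k_t$ is a single period index carrying the common time trend, and
$b_x$ measures how sensitive age $x$ is to that trend. The decomposition is
only identified up to scaling and shifting, so the usual restrictions are
imposed: $\sum_x b_x = 1$ and $\sum_t k_t = 0$. Under them $a_x$ is exactly
the row mean of the log-surface.

Estimation is the classical two-stage procedure:

1. **SVD stage.** Subtract $a_x$ from each row and take the leading singular
   triple $(\sigma_1, u_1, v_1)$ of the centred surface $D^*$. Setting
   $b = u_1 / \sum u_1$ and $k = \sigma_1 (\sum u_1)\, v_1$ preserves the
   rank-1 product while enforcing $\sum b = 1$. Because $a_x$ is the row
   mean, $D^*$ annihilates the constant vector and $v_1$ already sums to
   zero; the code re-centres $k$ anyway (see "Identification housekeeping").
   The share of the centred surface's variation captured by the first
   component, $\sigma_1^2 / \sum_i \sigma_i^2$, is reported as the
   percentage of variation (PV).
2. **Re-estimation stage.** The SVD minimises squared error in log-rates, so
   years with small populations can be poorly calibrated in *count* terms.
   Each $k_t$ is therefore re-estimated as the root of
   $$g(k) = \sum_x N_{x,t}\, e^{a_x + b_x k} - D_t,$$
   where $N_{x,t}$ are exposures and $D_t$ the observed total deaths of year
   $t$ (residuals are treated as zero inside the exponent — they are unknown
   at this point). When every $b_x > 0$, $g$ is strictly increasing and the
   root unique. The solver brackets the root starting from the first-stage
   $k_t \pm 10$, doubling the half-width (at most $2^{10}$ expansions —
   failure to bracket then becomes a clean error) and polishes with Newton
   steps; fitted yearly totals match observed totals to $10^{-8}$ relative.
   With mixed-sign $b_x$ multiple roots are possible; the root nearest the
   first-stage value is kept, with a warning.

**Identification housekeeping.** After both stages $k$ is re-centred to mean
zero and the offset $b_x \bar k$ is folded into $a_x$. This keeps the fitted
values $a_x + b_x k_t$ bit-identical while restoring $\sum k_t = 0$, which
the re-estimation stage otherwise breaks. A centred surface that is exactly
zero leaves $b$ unidentified; the documented convention is the symmetric one,
$b_x = 1/r$, $k_t = 0$.

**Degenerate and edge inputs.** Zero rates have no logarithm; they are
floored at a configurable `zero_floor` (default $10^{-8}$ per person-year)
and flagged in a mask so the SVD always sees a finite, complete matrix.
The sign convention is fixed by the normalisation: $b$ always sums to $+1$,
never $-1$, and $k$ flips with it.

## Forecasting the index

The index is projected with a random walk with drift — ARIMA(0,1,0) plus
constant, the canonical companion of this model. The drift is the mean first
difference and the innovation SD uses denominator $n-2$ (one observation
lost to differencing, one degree of freedom to the drift). Point forecasts
are $\hat k_{n+h} = k_n + h\hat d$ with standard error

$$\mathrm{se}_{k,h} = \sigma\sqrt{h + h^2/(n-1)},$$

which adds the uncertainty of the estimated drift (a mean of $n-1$
differences) to the accumulated innovation variance. This is exactly the
sampling distribution of the forecast error under the random walk, so the
$\pm 2\,\mathrm{se}$ band achieves near-nominal coverage — the test suite
verifies 88–99% empirically at $h = 5$. A pure-innovation convention
($\sigma\sqrt h$, `se_method = "innovation"`) is offered because both appear
in the applied literature. Other ARIMA orders are accepted via `order` and
delegated to `stats::arima()` behind the same contract; no automatic order
selection is attempted — a reproducible default beats a data-dependent one
for a model whose standard choice is so entrenched.

Rates are projected from the **observed** jump-off rates:

$$\hat m_{x,n+h} = m_{x,n}\, e^{\hat b_x (\hat k_{n+h} - \hat k_n)},
\qquad \text{PI: } \hat m_{x,n+h}\, e^{\pm 2 \hat b_x\,\mathrm{se}_{k,h}}.$$

Anchoring on the last observed rather than fitted rate is how this
projection identity is usually written, and it removes any jump-off bias in the
first forecast year at the cost of carrying that year's noise; a
`jumpoff = "fitted"` switch exposes the alternative. The multiplier is the
conventional round 2 rather than 1.96. Only index uncertainty enters the
interval — errors in $a_x$ and $b_x$ are deliberately not propagated, as
their contribution shrinks relative to the index's over the horizon. The
interval is exactly symmetric on the log scale and widens monotonically in
$h$ wherever $b_x \neq 0$.

## Life expectancy

Projected schedules are summarised with Chiang's abridged life table. For a
closed interval of width $n$, $q_x = n m_x / (1 + n(1-a_x)m_x)$ with
Chiang's $a_x$ (fraction of the interval lived by those dying in it)
defaulting to 0.5, the standard abridged-table value. The final interval is
open: $q = 1$ and $L = l/m$, the constant-hazard closure, so its rate must
be positive. From the radix $l_0 = 100{,}000$ the usual recurrences yield
$e_x = T_x / l_x$.

Two points deserve emphasis for cause-specific schedules:

* $e_0$ computed from, say, breast-cancer-only rates is a **summary index**
  of that schedule, not an all-cause life expectancy. With rates of order
  $10^{-4}$, almost everyone "survives" the closed intervals and the open
  interval contributes $1/m \approx$ thousands of years. Consequently the
  index — and especially its forecast error — is dominated by the open-age
  rate, and errors of hundreds of years on a base of thousands are the
  expected scale, not a defect. The error *moments across test years* remain
  a meaningful relative-accuracy comparison between strata, which is how the
  package uses them.
* The observed bands typically start at 25 or 50; `pad_to_birth = TRUE`
  prepends zero-mortality years down to age 0 so "at birth" is literal
  (adding exactly `start_age` years), while the default starts the table at
  the first supplied band. Which bridging a published table used is often
  unstated, so both modes are explicit.

## Forecast accuracy

Percent errors are $(\text{actual} - \text{predicted})/\text{actual}$, so
over-prediction is negative. MAPE is the mean absolute percent error
$\times 100$. The error table aggregates along both axes: per age across
years (MPE/MAPE) and per year across ages (IPE/IAPE, the age-integrated
signed/absolute errors — the per-year average of the age-error profile
normalised by the number of ages; this interpretation of the "integrated"
measures is flagged here because usage varies). Both the fraction and the
percentage scale are emitted under explicit names (`mape_frac`,
`mape_pct`), since published tables mix the two. Cells with zero actual
value cannot be scaled; they are excluded and counted, never propagated as
NaN. Life-expectancy forecast errors are signed (actual − forecast, years)
and summarised by their mean and population variance.

## The synthetic-data generator

`sim_spec()` describes a generative surface: true rates
$\mu_{x,t} = \exp(a_x + b_x k_t)$ with $k$ a seeded random walk with drift,
and deaths drawn per cell as Poisson($N\mu$) — the natural count model for
vital-event data — or negative binomial with mean $N\mu$ and variance
$N\mu(1 + N\mu/\theta)$ when overdispersion is wanted, or exactly $N\mu$
(`noise_model = "none"`), which makes the log-surface exactly rank-1 and
every estimation step exact.

The defaults are chosen once to emulate a screen-age/late-onset female
breast-cancer stratum and are the package's fixed study conditions: seven
5-year bands from 50–84 and thirty annual periods (1990–2019); log-rates
rising smoothly from about 2 to 12 per 100,000; exposure $10^6$
person-years per cell, the order of a 5-year female age band in a large
national population; drift $-0.5$ per year with innovation SD $0.3$, giving
index paths whose first SVD component captures roughly 85–95% of variation —
comparable to unsmoothed vital-registration surfaces. The early-onset preset
(`sim_spec_early_onset()`) differs only where the real strata differ: five
bands from 25–49 with rates of 0.5–4 per 100,000, so cells carry 10–40
deaths instead of 200–1,000 and the log-surface is visibly noisier. This
pairing reproduces, by construction, the qualitative pattern that the model
fits and forecasts the smoother, higher-count stratum better; the tests
check exactly that ordering and nothing finer.

What the generator does **not** emulate: cohort effects, age–period
interactions beyond rank 1, exposure trends, or the smoothing correlation
structure of modelled (rather than registered) mortality estimates. Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, not the model's adequacy for any particular real
population.

## Numerical choices

* Rates are per person-year internally; per-100,000 only at presentation.
* Surface CSVs are written with 17 significant digits, so a write–read
  round-trip is exact and pipeline runs are byte-reproducible under a fixed
  seed.
* The SVD stage needs no iteration or tolerance; the re-estimation root is
  polished with Newton steps to $\sim 10^{-14}$ relative.
* All simulation seeds pass through one helper that saves and restores the
  caller's RNG state, so library calls never perturb user scripts.
* Problem sizes in the test suite mirror the study conditions (7×30 and 5×30
  surfaces, 500-replicate Monte-Carlo checks for coverage and moments,
  50-schedule life-table sweeps) — large enough for the asserted bounds,
  small enough that the whole suite runs in seconds.

## Worked run

```{r, eval = FALSE}
library(lcmort)
report <- run_pipeline(lc_config(seed = 42))
report            # PV, within/out-of-sample MAPE, LE error moments
summary(report$fit)
plot(report$fit)  # a_x, b_x, k_t panels
```

## Known limitations

* Single-population only: no coherent multi-population variants, no
  Lee–Miller or Booth–Maindonald–Smith adjustments, no cohort extension.
* Estimation is SVD + total-death re-estimation; Poisson or
  negative-binomial maximum-likelihood fitting of the bilinear predictor is
  a declared extension point, not implemented.
* Prediction intervals ignore parameter uncertainty in $a_x, b_x$ and
  jump-off noise; no bootstrap alternative is provided.
* The GBD reader ignores published uncertainty intervals and performs no
  downloading; exports must be fetched manually.
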