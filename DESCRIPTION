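Package: lcmort
Title: Lee-Carter Modelling and Forecasting of Cause-Specific Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the Lee-Carter log-bilinear mortality model to age-by-year
    surfaces of cause-specific death rates, including the classical two-stage
    estimation (singular value decomposition followed by re-estimation of the
    mortality index against observed total deaths), random-walk-with-drift
    forecasting of the index with approximate prediction intervals, abridged
    life tables by Chiang's method, and within- and out-of-sample forecast
    accuracy measures (MPE, MAPE, IPE, IAPE, life-expectancy error moments).
    Includes a synthetic mortality-surface generator with Poisson or
    negative-binomial death counts so the whole pipeline can be exercised and
    validated without external data, and a reader for Global Burden of
    Disease results-tool CSV exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
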