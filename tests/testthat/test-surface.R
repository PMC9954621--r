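test_that("surface construction derives rates and enforces invariants", {
  d <- matrix(c(10, 20, 12, 22, 14, 24), 2, 3)
  e <- matrix(1e5, 2, 3)
  s <- mortality_surface(c(50, 55), 2000:2002, deaths = d, exposures = e)
  expect_equal(unname(s$rates), d / e)
  expect_equal(dim(s), c(2L, 3L))

  # rates + exposures back-compute deaths
  s2 <- mortality_surface(c(50, 55), 2000:2002, rates = d / e, exposures = e)
  expect_equal(s2$deaths, s$deaths)

  expect_error(mortality_surface(c(55, 50), 2000:2002, deaths = d, exposures = e),
               "strictly increasing")
  expect_error(mortality_surface(c(50, 55), c(2000, 2002, 2003), deaths = d,
                                 exposures = e), "consecutive")
  expect_error(mortality_surface(c(50, 55), 2000:2002, deaths = d,
                                 exposures = matrix(0, 2, 3)), "positive")
  expect_error(mortality_surface(c(50, 55), 2000:2002, deaths = d,
                                 exposures = e, rates = d), "inconsistent")
  expect_error(mortality_surface(c(50, 52), 2000:2002, deaths = d,
                                 exposures = e), "overlap")
})

test_that("log transform floors zeros, flags them, and inverts exactly elsewhere", {
  rates <- matrix(c(0.001, 0, exp(-5), 2e-9), 2, 2)
  s <- mortality_surface(c(25, 30), 2000:2001, rates = rates,
                         exposures = matrix(1, 2, 2))
  ls <- to_log_surface(s, zero_floor = 1e-8)
  expect_equal(ls$values[1, 1], log(0.001))
  expect_equal(ls$values[2, 1], log(1e-8))  # floored zero
  expect_equal(ls$values[1, 2], -5)
  expect_identical(unname(ls$zero_mask),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_true(all(is.finite(ls$values)))
  off <- !ls$zero_mask
  expect_equal(exp(ls$values)[off], s$rates[off])

  # constant surface of e^-5 maps to the constant -5
  s5 <- mortality_surface(c(25, 30), 2000:2001, rates = matrix(exp(-5), 2, 2),
                          exposures = matrix(1, 2, 2))
  expect_equal(unname(to_log_surface(s5)$values), matrix(-5, 2, 2))
  expect_error(to_log_surface(s, zero_floor = 0), "positive")
})

test_that("train/test split partitions the year axis", {
  spec <- sim_spec(seed = 3)
  s <- simulate_surface(spec)           # 1990-2019
  sp <- split_train_test(s, 2010)
  expect_s3_class(sp, "split_surfaces")
  expect_equal(ncol(sp$train$rates), 21)
  expect_equal(ncol(sp$test$rates), 9)
  expect_equal(max(sp$train$years), 2010)
  expect_equal(min(sp$test$years), 2011)
  # partition: concatenating columns restores the parent
  expect_equal(cbind(sp$train$deaths, sp$test$deaths), s$deaths,
               ignore_attr = TRUE)
  expect_equal(c(sp$train$years, sp$test$years), s$years)
  expect_length(intersect(sp$train$years, sp$test$years), 0)

  # boundary: split at last year - 1 leaves one test column
  sp2 <- split_train_test(s, 2018)
  expect_equal(ncol(sp2$test$rates), 1)
  expect_error(split_train_test(s, 2019), "inside")
  expect_error(split_train_test(s, 1989), "inside")
})

test_that("long-format CSV round-trips a surface exactly", {
  s <- simulate_surface(sim_spec(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(s, path)
  s2 <- read_surface_csv(path, label = s$label)
  expect_equal(s2$deaths, s$deaths, tolerance = 1e-12)
  expect_equal(s2$exposures, s$exposures, tolerance = 1e-12)
  expect_equal(s2$rates, s$rates, tolerance = 1e-12)
  expect_equal(s2$ages, s$ages)
  expect_equal(s2$widths, s$widths)
  expect_equal(s2$years, s$years)
})

test_that("GBD-dialect reader pivots, selects metric, and rejects bad grids", {
  toy <- data.frame(
    measure = "Deaths", location = "China", sex = "Female",
    age = rep(c("50 to 54", "55 to 59"), each = 3),
    cause = "Breast cancer", metric = "Rate",
    year = rep(2000:2002, 2),
    val = c(20, 21, 22, 30, 31, 32))   # per 100,000
  s <- read_gbd_csv(toy, metric = "Rate")
  expect_equal(dim(s), c(2L, 3L))
  expect_equal(s$ages, c(50, 55))
  expect_equal(s$widths, c(5, 5))
  expect_equal(unname(s$rates[, 1]), c(20, 30) / 1e5)
  expect_equal(s$label, "China")

  # deaths path with a population companion table
  pop <- toy; pop$metric <- "Number"; pop$val <- rep(c(2e5, 1e5), each = 3)
  cnt <- toy; cnt$val <- c(40, 42, 44, 30, 31, 32); cnt$metric <- "Deaths"
  s2 <- read_gbd_csv(rbind(cnt, toy), metric = "Deaths",
                     population = pop)
  expect_equal(unname(s2$rates[, 1]), c(40 / 2e5, 30 / 1e5))

  expect_error(read_gbd_csv(toy[-2, ], metric = "Rate"), "missing cell")
  expect_error(read_gbd_csv(rbind(toy, toy[1, ]), metric = "Rate"), "duplicate")
  expect_error(read_gbd_csv(toy[, setdiff(names(toy), "val")], metric = "Rate"),
               "configuration")
  bad <- toy; bad$year <- rep(c(2000, 2002, 2004), 2)
  expect_error(read_gbd_csv(bad, metric = "Rate"), "contiguous")
  expect_error(read_gbd_csv(cnt, metric = "Deaths"), "population")
  # age-range restriction
  s3 <- read_gbd_csv(toy, metric = "Rate", age_range = c(55, 59))
  expect_equal(s3$ages, 55)
})
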