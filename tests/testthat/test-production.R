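nat_tbl <- function(years, prod, country = "C01") {
  tibble::tibble(country_id = country, year = years, production = prod)
}

reg_tbl <- function(regions, years, prod, country = "C01") {
  tibble::tibble(region_id = rep(regions, each = length(years)),
                 country_id = country,
                 year = rep(years, length(regions)),
                 production = prod)
}

test_that("the national gap is the signed national-minus-regional difference", {
  nat <- nat_tbl(2000, 100)
  expect_equal(national_gap(nat, reg_tbl(c("A", "B"), 2000, c(50, 30)), 2000),
               20)
  expect_equal(national_gap(nat, reg_tbl(c("A", "B"), 2000, c(60, 40)), 2000),
               0)
  expect_equal(national_gap(nat_tbl(2000, 90),
                            reg_tbl(c("A", "B"), 2000, c(50, 45)), 2000),
               -5)
  # missing regional records are excluded from the sum
  expect_equal(national_gap(nat, reg_tbl(c("A", "B"), 2000, c(80, NA)), 2000),
               20)
  expect_error(national_gap(nat, reg_tbl("A", 2001, 10), 2001),
               class = "gap_undefined")
})

test_that("gap-filling follows the sign of the gap", {
  areas <- tibble::tibble(region_id = c("A", "B", "C"),
                          harvest_area_ha = c(30, 10, 0))
  # positive gap: proportional to harvest area among missing regions
  reg <- reg_tbl(c("A", "B", "C"), 2000, c(NA, NA, 80))
  out <- fill_missing(nat_tbl(2000, 100), reg, areas, 2000)
  expect_equal(out$production[out$region_id == "A"], 15)
  expect_equal(out$production[out$region_id == "B"], 5)
  expect_identical(out$fill_flag[out$region_id %in% c("A", "B")],
                   c("filled", "filled"))
  expect_equal(sum(out$production), 100) # conservation

  # zero gap: missing records set to zero
  reg <- reg_tbl(c("A", "B"), 2000, c(100, NA))
  out <- fill_missing(nat_tbl(2000, 100), reg, areas, 2000)
  expect_equal(out$production[out$region_id == "B"], 0)
  expect_identical(out$fill_flag[out$region_id == "B"], "zero-filled")

  # negative gap: records remain missing
  reg <- reg_tbl(c("A", "B"), 2000, c(105, NA))
  out <- fill_missing(nat_tbl(2000, 100), reg, areas, 2000)
  expect_true(is.na(out$production[out$region_id == "B"]))
  expect_identical(out$fill_flag[out$region_id == "B"], "left-missing")

  # positive gap but zero harvest area among missing: cannot allocate
  reg <- reg_tbl(c("A", "C"), 2000, c(80, NA))
  areas0 <- tibble::tibble(region_id = c("A", "C"),
                           harvest_area_ha = c(30, 0))
  out <- fill_missing(nat_tbl(2000, 100), reg, areas0, 2000)
  expect_true(is.na(out$production[out$region_id == "C"]))
})

test_that("panel-level filling conserves national totals and is idempotent", {
  cfg <- scenario_config(n_regions = 10, n_countries = 2,
                         missing_rate = 0.2, seed = 42)
  sim <- simulate_scenario(cfg)
  f1 <- fill_production(sim$regional, sim$national, sim$areas)
  sums <- dplyr::summarise(dplyr::group_by(f1$data, country_id, year),
                           s = sum(production), .groups = "drop")
  j <- dplyr::left_join(sums, sim$national, by = c("country_id", "year"))
  expect_true(all(abs(j$s - j$production) <= 1e-9 * pmax(1, j$production)))
  # idempotence: a second pass changes no value
  f2 <- fill_production(f1$data[, c("region_id", "country_id", "year",
                                    "production")],
                        sim$national, sim$areas)
  expect_equal(f2$data$production, f1$data$production)

  # no-op without missingness
  sim0 <- simulate_scenario(scenario_config(n_regions = 5,
                                            missing_rate = 0, seed = 7))
  f0 <- fill_production(sim0$regional, sim0$national, sim0$areas)
  expect_identical(unique(f0$data$fill_flag), "observed")
  j0 <- dplyr::left_join(f0$data, sim0$regional,
                         by = c("region_id", "country_id", "year"))
  expect_equal(j0$production.x, j0$production.y)
})

test_that("years without a national record are skipped and logged", {
  reg <- reg_tbl(c("A", "B"), 2000:2001, c(50, NA, 30, NA))
  nat <- nat_tbl(2000, 100)
  areas <- tibble::tibble(region_id = c("A", "B"), harvest_area_ha = c(1, 1))
  out <- fill_production(reg, nat, areas)
  d <- out$data
  expect_false(is.na(d$production[d$region_id == "B" & d$year == 2000]))
  expect_true(is.na(d$production[d$region_id == "B" & d$year == 2001]))
  expect_true("no-national-record" %in% out$log$event)
})

test_that("the indicator detrends, labels by anomaly sign, and filters", {
  yrs <- 1990:2014 # 25 years
  # perfect line: residuals are numerically zero -> degenerate, excluded
  ind <- make_indicator(tibble::tibble(year = yrs,
                                       production = 2 * (yrs - 1989)), "r")
  expect_false(ind$ok)
  expect_identical(ind$reason, "degenerate")

  # 19 and exactly 20 years are excluded; 21 years pass
  set.seed(1)
  for (n in c(19, 20)) {
    ind <- make_indicator(tibble::tibble(year = 2000 + seq_len(n),
                                         production = 100 + rnorm(n)), "r")
    expect_false(ind$ok)
    expect_identical(ind$reason, "too_few_years")
  }
  ind <- make_indicator(tibble::tibble(year = 2000 + 1:21,
                                       production = 100 + rnorm(21)), "r")
  expect_true(ind$ok)
  expect_identical(nrow(ind$data), 21L)

  # trendless series: a year above the mean is labelled high
  prod <- rep(10, 25)
  prod[c(3, 10)] <- c(12, 8) # keep the mean at 10 + small imbalance
  prod[17] <- 10 + (10 * 25 - sum(prod[-17])) # rebalance mean to exactly 10
  ind <- make_indicator(tibble::tibble(year = yrs, production = prod), "r")
  expect_true(ind$ok)
  expect_false(ind$detrended)
  expect_identical(ind$data$label[ind$data$year == yrs[3]], "high")
  expect_identical(ind$data$label[ind$data$year == yrs[10]], "low")

  # a strong trend is removed when its slope is significant
  set.seed(2)
  trended <- 100 + 3 * seq_along(yrs) + rnorm(25)
  ind <- make_indicator(tibble::tibble(year = yrs, production = trended), "r")
  expect_true(ind$detrended)
  expect_lt(ind$trend_p, 0.1)
})

test_that("labels are invariant to level shifts and balanced under noise", {
  yrs <- 1980:2010
  set.seed(3)
  base <- 50 + rnorm(31, sd = 5)
  i1 <- make_indicator(tibble::tibble(year = yrs, production = base), "r")
  i2 <- make_indicator(tibble::tibble(year = yrs, production = base + 1000),
                       "r")
  expect_identical(i1$data$label, i2$data$label)
  expect_equal(i1$data$anomaly, i2$data$anomaly)

  # pure-noise series give roughly balanced labels in expectation
  set.seed(4)
  frac_low <- replicate(200, {
    ind <- make_indicator(tibble::tibble(year = yrs,
                                         production = 100 + rnorm(31)), "r")
    mean(ind$data$label == "low")
  })
  expect_gt(mean(frac_low), 0.45)
  expect_lt(mean(frac_low), 0.55)
})
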