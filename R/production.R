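#' Read regional, national and harvest-area production tables
#'
#' Regional records are annual production per region in 1000 t fresh
#' weight (columns `region_id`, `country_id`, `year`, `production`; empty
#' cells are missing records). National records carry `country_id`, `year`,
#' `production`; harvest areas carry static `region_id`, `harvest_area_ha`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_regional_production <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("region_id", "country_id", "year", "production"),
                  "regional production table")
  check_nonnegative(df$production, "regional production")
  tibble::as_tibble(df)
}

#' @rdname read_regional_production
#' @export
read_national_production <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("country_id", "year", "production"),
                  "national production table")
  check_nonnegative(df$production, "national production")
  tibble::as_tibble(df)
}

#' @rdname read_regional_production
#' @export
read_harvest_areas <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("region_id", "harvest_area_ha"), "harvest area table")
  check_nonnegative(df$harvest_area_ha, "harvest area")
  tibble::as_tibble(df)
}

check_nonnegative <- function(x, what) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad) > 0) {
    fc_stop(sprintf("negative %s at row(s): %s", what,
                    paste(utils::head(bad, 5), collapse = ", ")),
            "schema_error")
  }
  invisible(x)
}

#' National production gap for one year
#'
#' The signed difference between a country's national production total and
#' the sum of its non-missing regional records for one year. A positive gap
#' is production registered nationally but unaccounted for regionally; it
#' is what proportional gap-filling allocates to missing regions.
#'
#' @param national National series for one country (columns `country_id`,
#'   `year`, `production`).
#' @param regional Regional records for the same country (columns
#'   `region_id`, `year`, `production`; `NA` = missing).
#' @param year The year.
#' @return The signed gap in 1000 t (may be negative).
#' @export
national_gap <- function(national, regional, year) {
  p_n <- national$production[national$year == year]
  p_n <- p_n[!is.na(p_n)]
  if (length(p_n) == 0) {
    fc_stop(sprintf("no national record for year %s", year), "gap_undefined")
  }
  if (length(p_n) > 1) {
    fc_stop(sprintf("multiple national records for year %s", year),
            "schema_error")
  }
  reg <- regional$production[regional$year == year]
  p_n - sum(reg, na.rm = TRUE)
}

#' Fill missing regional records for one year from the national gap
#'
#' Implements proportional gap-filling. With `gap` the national gap of
#' [national_gap()] for the year:
#' * `gap > 0`: each missing region receives
#'   `gap * HA_i / sum(HA over missing regions)` (flag `"filled"`);
#' * `gap == 0` (to tolerance): missing regions are set to 0
#'   (flag `"zero-filled"`);
#' * `gap < 0`: missing regions stay missing (flag `"left-missing"`).
#'
#' If the missing regions have zero total harvest area the gap cannot be
#' allocated and the records stay missing.
#'
#' @inheritParams national_gap
#' @param areas Harvest-area table (`region_id`, `harvest_area_ha`).
#' @param year The year to fill.
#' @return The regional table with `production` updated for `year` and a
#'   `fill_flag` column (`observed`, `filled`, `zero-filled`,
#'   `left-missing`) set for that year.
#' @export
fill_missing <- function(national, regional, areas, year) {
  if (!"fill_flag" %in% names(regional)) {
    regional$fill_flag <- ifelse(is.na(regional$production),
                                 "left-missing", "observed")
  }
  sel <- regional$year == year
  miss <- sel & is.na(regional$production)
  if (!any(miss)) return(regional)
  gap <- national_gap(national, regional, year)
  nat <- national$production[national$year == year]
  tol <- 1e-9 * max(1, abs(nat))
  if (gap > tol) {
    ha <- areas$harvest_area_ha[match(regional$region_id[miss],
                                      areas$region_id)]
    ha[is.na(ha)] <- 0
    if (sum(ha) <= 0) {
      return(regional) # cannot allocate; stays left-missing
    }
    regional$production[miss] <- gap * ha / sum(ha)
    regional$fill_flag[miss] <- "filled"
  } else if (abs(gap) <= tol) {
    regional$production[miss] <- 0
    regional$fill_flag[miss] <- "zero-filled"
  }
  # gap < 0: unaltered, flag stays left-missing
  regional
}

#' Gap-fill all regional production records from national totals
#'
#' Completes the regional panel to a full region x year grid per country
#' (a region-year absent from the input counts as missing), then applies
#' [fill_missing()] country by country and year by year. Years without a
#' national record are skipped and logged.
#'
#' @param regional Regional production table (`region_id`, `country_id`,
#'   `year`, `production`).
#' @param national National production table (`country_id`, `year`,
#'   `production`).
#' @param areas Harvest-area table (`region_id`, `harvest_area_ha`).
#' @return A list with `data` (completed regional tibble with `fill_flag`
#'   provenance) and `log` (one row per country-year event that prevented
#'   or altered filling).
#' @export
fill_production <- function(regional, national, areas) {
  require_columns(regional, c("region_id", "country_id", "year", "production"),
                  "regional production table")
  require_columns(national, c("country_id", "year", "production"),
                  "national production table")
  require_columns(areas, c("region_id", "harvest_area_ha"),
                  "harvest area table")

  out <- list()
  log <- list()
  for (cc in unique(regional$country_id)) {
    reg_c <- regional[regional$country_id == cc, , drop = FALSE]
    nat_c <- national[national$country_id == cc, , drop = FALSE]
    years <- sort(unique(c(reg_c$year, nat_c$year)))
    grid <- tidyr::expand_grid(region_id = unique(reg_c$region_id),
                               year = years)
    grid$country_id <- cc
    grid <- dplyr::left_join(grid,
                             reg_c[, c("region_id", "year", "production")],
                             by = c("region_id", "year"))
    grid$fill_flag <- ifelse(is.na(grid$production),
                             "left-missing", "observed")
    for (yy in years) {
      miss <- grid$year == yy & is.na(grid$production)
      if (!any(miss)) next
      if (!any(nat_c$year == yy & !is.na(nat_c$production))) {
        log[[length(log) + 1]] <- tibble::tibble(
          country_id = cc, year = yy, event = "no-national-record",
          n_missing = sum(miss))
        next
      }
      gap <- national_gap(nat_c, grid, yy)
      grid <- fill_missing(nat_c, grid, areas, yy)
      event <- if (gap > 0 && all(grid$fill_flag[miss] == "left-missing")) {
        "zero-area-cannot-allocate"
      } else if (gap < 0) {
        "negative-gap-left-missing"
      } else {
        NA_character_
      }
      if (!is.na(event)) {
        log[[length(log) + 1]] <- tibble::tibble(
          country_id = cc, year = yy, event = event, n_missing = sum(miss))
      }
    }
    out[[length(out) + 1]] <- grid
  }
  data <- dplyr::bind_rows(out)[, c("region_id", "country_id", "year",
                                    "production", "fill_flag")]
  log <- if (length(log) > 0) dplyr::bind_rows(log) else
    tibble::tibble(country_id = character(), year = integer(),
                   event = character(), n_missing = integer())
  list(data = data, log = log)
}

#' Binarize a regional production series into high/low years
#'
#' Production anomalies are deviations from the multiyear mean, after
#' removing a linear trend when the OLS slope of `production ~ year` is
#' significant (two-sided t-test, p <= `trend_alpha`). Negative anomalies
#' are labelled `"low"`, non-negative anomalies `"high"` (an exact zero is
#' a measure-zero tie broken towards `"high"`). Regions with `min_years`
#' or fewer labelled years, or with numerically zero anomaly variance, are
#' excluded rather than labelled.
#'
#' @param series Tibble with columns `year` and `production` (`NA` rows are
#'   dropped before fitting).
#' @param region_id Optional identifier carried through to the result.
#' @param trend_alpha Significance level for detrending (default 0.1).
#' @param min_years Exclusive minimum number of labelled years (default 20,
#'   i.e. at least 21 years are required).
#' @return A `production_indicator` object. When the region is usable,
#'   `$ok` is `TRUE` and `$data` holds `year`, `anomaly` (1000 t) and
#'   `label`; otherwise `$ok` is `FALSE` and `$reason` is one of
#'   `"too_few_years"`, `"degenerate"`.
#' @export
make_indicator <- function(series, region_id = NULL, trend_alpha = 0.1,
                           min_years = 20) {
  require_columns(series, c("year", "production"), "production series")
  ok <- series[!is.na(series$production), , drop = FALSE]
  ok <- ok[order(ok$year), , drop = FALSE]
  n <- nrow(ok)
  excluded <- function(reason) {
    structure(list(region_id = region_id, ok = FALSE, reason = reason,
                   n_years = n),
              class = "production_indicator")
  }
  if (n <= min_years) return(excluded("too_few_years"))

  fit <- stats::lm(production ~ year, data = ok)
  coefs <- stats::coef(summary(fit))
  trend_p <- if (nrow(coefs) >= 2) coefs["year", "Pr(>|t|)"] else NA_real_
  detrended <- !is.na(trend_p) && trend_p <= trend_alpha
  anomaly <- if (detrended) {
    as.numeric(stats::residuals(fit))
  } else {
    ok$production - mean(ok$production)
  }
  if (max(abs(anomaly)) < 1e-8 * max(1, max(abs(ok$production)))) {
    return(excluded("degenerate"))
  }
  structure(list(
    region_id = region_id, ok = TRUE,
    data = tibble::tibble(year = ok$year, anomaly = anomaly,
                          label = ifelse(anomaly < 0, "low", "high")),
    detrended = detrended, trend_p = trend_p, n_years = n
  ), class = "production_indicator")
}

#' @export
print.production_indicator <- function(x, ...) {
  id <- x$region_id %||% "<unnamed>"
  if (!x$ok) {
    cat(sprintf("<production_indicator> %s: excluded (%s), %d year(s)\n",
                id, x$reason, x$n_years))
  } else {
    cat(sprintf(
      "<production_indicator> %s: %d years, %d low / %d high, %s (trend p = %.3g)\n",
      id, x$n_years, sum(x$data$label == "low"), sum(x$data$label == "high"),
      if (x$detrended) "detrended" else "mean-removed", x$trend_p))
  }
  invisible(x)
}
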