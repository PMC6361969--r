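# Seeded synthetic-data generator: coupled climate-index and production
# panels with known ground truth, so every pipeline stage is testable
# without any external download.

#' Configuration of a synthetic scenario
#'
#' Defines the study conditions a scenario emulates: a 39-year panel
#' (matching the 1975--2013 span of the feature years), five independent
#' standardized monthly AR(1) index series, and regional production built
#' as base level + linear trend + an index-driven anomaly + noise, with
#' EUROSTAT-style missingness recoverable from national totals.
#'
#' The index effect is `effect_size` noise standard deviations of class
#' separation: with the default step link, years whose driving-index
#' feature exceeds zero lose `effect_size * noise_sd / 2` and the others
#' gain the same amount, so `effect_size = 0` is an exact null and
#' `effect_size = 4` gives near-separated classes. A `"linear"` link
#' (`-effect_size * noise_sd * feature / 2`) is available for
#' misspecification studies.
#'
#' @param n_years Years in the panel (default 39; at least 21 so regions
#'   pass the length filter).
#' @param start_year First year (default 1975).
#' @param n_regions Number of regions (default 20).
#' @param n_countries Regions are assigned to this many countries
#'   round-robin (default 4).
#' @param ar1_rho Lag-1 autocorrelation of the monthly index series, in
#'   \[0, 1) (default 0.3).
#' @param driving_index Which index drives production (default `"NAO"`);
#'   `"none"` disables the climate effect regardless of `effect_size`.
#' @param driving_lead Lead time of the driving feature, 1--6 (default 3).
#' @param effect_size Class separation in noise SDs (default 4).
#' @param trend_slope Linear production trend in 1000 t per year
#'   (default 0.5).
#' @param noise_sd Production noise SD in 1000 t (default 10).
#' @param missing_rate Share of region-years blanked to missing
#'   (default 0.1).
#' @param link `"step"` (default) or `"linear"` index-to-anomaly map.
#' @param seed Integer master seed.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_years = 39, start_year = 1975, n_regions = 20,
                            n_countries = 4, ar1_rho = 0.3,
                            driving_index = "NAO", driving_lead = 3,
                            effect_size = 4, trend_slope = 0.5,
                            noise_sd = 10, missing_rate = 0.1,
                            link = c("step", "linear"), seed = 1) {
  link <- match.arg(link)
  if (n_years < 21) fc_stop("`n_years` must be at least 21", "invalid_argument")
  if (ar1_rho < 0 || ar1_rho >= 1) {
    fc_stop("`ar1_rho` must be in [0, 1)", "invalid_argument")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    fc_stop("`missing_rate` must be in [0, 1)", "invalid_argument")
  }
  if (effect_size < 0) fc_stop("`effect_size` must be >= 0",
                               "invalid_argument")
  if (!identical(driving_index, "none")) {
    if (!driving_index %in% index_names()) {
      fc_stop(sprintf("`driving_index` must be one of %s or 'none'",
                      paste(index_names(), collapse = ", ")),
              "invalid_argument")
    }
    lead_window(driving_lead) # validates
  }
  structure(list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_regions = as.integer(n_regions), n_countries = as.integer(n_countries),
    ar1_rho = ar1_rho, driving_index = driving_index,
    driving_lead = as.integer(driving_lead), effect_size = effect_size,
    trend_slope = trend_slope, noise_sd = noise_sd,
    missing_rate = missing_rate, link = link, seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Names of the five climate-variability indices
#' @return Character vector `SOI, NAO, EA, EAWR, SCA`.
#' @export
index_names <- function() c("SOI", "NAO", "EA", "EAWR", "SCA")

#' Generate standardized monthly AR(1) index panels
#'
#' Five independent monthly AR(1) series with lag-1 autocorrelation
#' `ar1_rho` and unit marginal variance, standardized to mean 0 / SD 1
#' over the panel. Reproducible by `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A long tibble (`index_name`, `year`, `month`, `value`) valid
#'   under [validate_climate_indices()].
#' @export
gen_indices <- function(config) {
  n_months <- 12L * config$n_years
  rho <- config$ar1_rho
  years <- config$start_year + seq_len(config$n_years) - 1L
  with_seed(derive_seed(config$seed, "indices"), {
    panels <- lapply(index_names(), function(nm) {
      e <- stats::rnorm(n_months)
      x <- numeric(n_months)
      x[1] <- e[1]
      scale_innov <- sqrt(1 - rho^2)
      for (t in seq_len(n_months)[-1]) {
        x[t] <- rho * x[t - 1] + scale_innov * e[t]
      }
      x <- (x - mean(x)) / stats::sd(x)
      tibble::tibble(index_name = nm,
                     year = rep(years, each = 12L),
                     month = rep(1:12, config$n_years),
                     value = x)
    })
    dplyr::bind_rows(panels)
  })
}

#' Generate coupled regional production panels
#'
#' Builds per-region annual production as
#' `base + trend_slope * (year - start_year) + signal(year) + noise`,
#' where the signal is the configured function of the driving index's
#' 3-month feature at the driving lead (shared by all regions; per-region
#' noise is independent). Harvest areas are static and production bases
#' scale with them, so proportional gap-filling is coherent. National
#' series are the exact regional sums of the pre-blanking truth, which
#' makes gap-filling recoverable; a `missing_rate` share of region-years
#' is then blanked.
#'
#' @param config A [scenario_config()].
#' @param indices Index panel from [gen_indices()] (regenerated when
#'   omitted).
#' @return A list with `regional`, `national`, `areas` tibbles (the reader
#'   schemas of the production module) and `truth`, which records the
#'   planted driver, the feature series, the pre-blanking production and
#'   the blanked cells.
#' @export
gen_production <- function(config, indices = NULL) {
  indices <- indices %||% gen_indices(config)
  years <- config$start_year + seq_len(config$n_years) - 1L

  if (identical(config$driving_index, "none") || config$effect_size == 0) {
    signal <- rep(0, config$n_years)
    feature <- rep(NA_real_, config$n_years)
  } else {
    feats <- compute_lead_features(indices, config$driving_lead, quiet = TRUE)
    stopifnot(identical(feats$year, years))
    feature <- feats[[tolower(config$driving_index)]]
    amp <- config$effect_size * config$noise_sd
    signal <- if (config$link == "step") {
      ifelse(feature > 0, -amp / 2, amp / 2)
    } else {
      -amp * feature / 2
    }
  }

  nr <- config$n_regions
  ny <- config$n_years
  with_seed(derive_seed(config$seed, "production"), {
    area <- round(stats::runif(nr, 2000, 20000))
    yield <- stats::runif(nr, 0.04, 0.07) # 1000 t per ha
    base <- area * yield
    country <- sprintf("C%02d", rep_len(seq_len(config$n_countries), nr))
    region <- sprintf("%s-R%02d", country, seq_len(nr))
    noise <- matrix(stats::rnorm(nr * ny, sd = config$noise_sd), nr, ny)
    truth_prod <- outer(base, rep(1, ny)) +
      outer(rep(1, nr), config$trend_slope * (years - config$start_year)) +
      outer(rep(1, nr), signal) + noise
    truth_prod[truth_prod < 0] <- 0
    blank <- matrix(stats::runif(nr * ny) < config$missing_rate, nr, ny)

    regional <- tibble::tibble(
      region_id = rep(region, each = ny),
      country_id = rep(country, each = ny),
      year = rep(years, nr),
      production = as.vector(t(ifelse(blank, NA, truth_prod))))
    national <- regional
    national$production <- as.vector(t(truth_prod))
    national <- national |>
      dplyr::group_by(country_id, year) |>
      dplyr::summarise(production = sum(production), .groups = "drop")
    areas <- tibble::tibble(region_id = region, harvest_area_ha = area)
    truth <- list(
      driving_index = config$driving_index,
      driving_lead = config$driving_lead,
      effect_size = config$effect_size,
      link = config$link,
      feature = tibble::tibble(year = years, feature = feature,
                               signal = signal),
      production = tibble::tibble(
        region_id = rep(region, each = ny),
        year = rep(years, nr),
        production = as.vector(t(truth_prod)),
        blanked = as.vector(t(blank))))
    list(regional = regional, national = national, areas = areas,
         truth = truth)
  })
}

#' Simulate a full scenario and optionally write it to disk
#'
#' Generates the index panel and the coupled production tables and, when
#' `dir` is given, writes them as the CSV schemas the readers consume
#' (`indices.csv`, `production_regional.csv`, `production_national.csv`,
#' `harvest_areas.csv`) plus a `truth.json` sidecar with the planted
#' ground truth.
#'
#' @param config A [scenario_config()].
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list with `indices`, `regional`, `national`,
#'   `areas`, `truth`, `config` and (when written) `files`.
#' @export
simulate_scenario <- function(config, dir = NULL) {
  indices <- gen_indices(config)
  prod <- gen_production(config, indices)
  out <- c(list(indices = indices), prod, list(config = config))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      indices = file.path(dir, "indices.csv"),
      regional = file.path(dir, "production_regional.csv"),
      national = file.path(dir, "production_national.csv"),
      areas = file.path(dir, "harvest_areas.csv"),
      truth = file.path(dir, "truth.json"))
    readr::write_csv(indices, files$indices)
    readr::write_csv(prod$regional, files$regional)
    readr::write_csv(prod$national, files$national)
    readr::write_csv(prod$areas, files$areas)
    jsonlite::write_json(
      c(prod$truth[c("driving_index", "driving_lead", "effect_size",
                     "link")],
        list(feature = prod$truth$feature,
             production = prod$truth$production,
             config = unclass(config))),
      files$truth, auto_unbox = TRUE, digits = NA, na = "null")
    out$files <- files
  }
  invisible(out)
}
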