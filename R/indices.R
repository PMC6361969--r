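#' Lead-time averaging window
#'
#' Forecasts are anchored to a harvest season starting in September, so a
#' lead time of `k` months points at the 3-month index-averaging window that
#' ends `k` months before September: lead 6 averages January--March, lead 5
#' February--April, and so on down to lead 1 averaging June--August. All six
#' windows fall inside one calendar year; no cross-year windows are formed.
#'
#' @param lead Integer lead time in months, between 1 and 6.
#' @return A `lead_window` object: a list with `lead` and the ordered
#'   integer `months` (Jan = 1) of the averaging window.
#' @examples
#' lead_window(6)   # January-March
#' lead_window(1)   # June-August
#' @export
lead_window <- function(lead) {
  if (!is.numeric(lead) || length(lead) != 1L || is.na(lead) ||
      lead != round(lead) || lead < 1 || lead > 6) {
    fc_stop("`lead` must be a single integer between 1 and 6",
            "invalid_argument")
  }
  months <- (7L - as.integer(lead)):(9L - as.integer(lead))
  structure(list(lead = as.integer(lead), months = months),
            class = "lead_window")
}

#' @export
print.lead_window <- function(x, ...) {
  cat(sprintf("<lead_window> lead %d: %s\n", x$lead,
              paste(month.abb[x$months], collapse = "-")))
  invisible(x)
}

#' Read a monthly climate-index table
#'
#' Reads a delimited table with columns `index_name`, `year`, `month`,
#' `value` holding standardized monthly climate-oscillation indices (e.g.
#' SOI, NAO, EA, EA/WR, SCA). Fixed-width agency layouts should be converted
#' to this long CSV form first; any separator that [readr::read_csv()]
#' accepts via `delim` works through `...`.
#'
#' @param path Path to a CSV file.
#' @param ... Passed on to [readr::read_csv()].
#' @return A validated tibble (see [validate_climate_indices()]).
#' @export
read_climate_indices <- function(path, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
  validate_climate_indices(df)
}

#' Validate a monthly climate-index table
#'
#' Checks the schema and the panel invariants: months within 1--12, finite
#' values, and at most one record per (index, year, month).
#'
#' @param df A data frame with columns `index_name`, `year`, `month`, `value`.
#' @return The input as a tibble, invisibly valid; errors of class
#'   `schema_error` otherwise.
#' @export
validate_climate_indices <- function(df) {
  require_columns(df, c("index_name", "year", "month", "value"),
                  "climate index table")
  df <- tibble::as_tibble(df)
  bad_month <- which(is.na(df$month) | df$month < 1 | df$month > 12 |
                       df$month != round(df$month))
  if (length(bad_month) > 0) {
    fc_stop(sprintf("invalid month at row(s): %s",
                    paste(utils::head(bad_month, 5), collapse = ", ")),
            "schema_error")
  }
  if (any(!is.finite(df$value))) {
    fc_stop(sprintf("non-finite index value at row(s): %s",
                    paste(utils::head(which(!is.finite(df$value)), 5),
                          collapse = ", ")),
            "schema_error")
  }
  key <- paste(df$index_name, df$year, df$month)
  if (anyDuplicated(key)) {
    fc_stop(sprintf("duplicated (index, year, month) at row(s): %s",
                    paste(utils::head(which(duplicated(key)), 5),
                          collapse = ", ")),
            "schema_error")
  }
  df
}

#' Compute 3-month lead-time features
#'
#' For one lead time, averages each index over its 3-month window and
#' returns one feature per index per year. A year enters the output only if
#' all three window months are present for every index; incomplete years are
#' dropped (and reported via a message), never interpolated.
#'
#' @param indices A long index table as returned by
#'   [read_climate_indices()] (columns `index_name`, `year`, `month`,
#'   `value`).
#' @param lead Integer lead 1--6, or a [lead_window()] object.
#' @param years Optional integer vector restricting the years considered.
#' @param quiet Suppress the dropped-years message.
#' @return A tibble with column `year` followed by one lower-cased column
#'   per index (e.g. `soi`, `nao`, `ea`, `eawr`, `sca`), in order of first
#'   appearance in `indices`. The lead window is attached as attribute
#'   `"lead"`.
#' @export
compute_lead_features <- function(indices, lead, years = NULL, quiet = FALSE) {
  win <- if (inherits(lead, "lead_window")) lead else lead_window(lead)
  indices <- validate_climate_indices(indices)
  idx_names <- unique(indices$index_name)

  sub <- indices[indices$month %in% win$months, , drop = FALSE]
  if (!is.null(years)) sub <- sub[sub$year %in% years, , drop = FALSE]

  agg <- sub |>
    dplyr::group_by(index_name, year) |>
    dplyr::summarise(n_months = dplyr::n(), feature = mean(value),
                     .groups = "drop") |>
    dplyr::filter(n_months == 3L)

  wide <- tidyr::pivot_wider(agg[, c("index_name", "year", "feature")],
                             names_from = "index_name",
                             values_from = "feature")
  # enforce one column per supplied index, in first-appearance order
  missing_idx <- setdiff(idx_names, names(wide))
  for (nm in missing_idx) wide[[nm]] <- NA_real_
  wide <- wide[, c("year", idx_names), drop = FALSE]

  complete <- stats::complete.cases(wide)
  candidate_years <- sort(unique(sub$year))
  dropped <- setdiff(candidate_years, wide$year[complete])
  if (length(dropped) > 0 && !quiet) {
    message(sprintf("lead %d: dropped %d year(s) with incomplete windows: %s",
                    win$lead, length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")))
  }
  out <- wide[complete, , drop = FALSE]
  out <- out[order(out$year), , drop = FALSE]
  if (nrow(out) == 0) {
    fc_stop("no year has complete 3-month windows for all indices",
            "empty_features")
  }
  names(out) <- c("year", tolower(idx_names))
  attr(out, "lead") <- win
  out
}

#' Write a lead-time feature table to CSV
#'
#' @param features Output of [compute_lead_features()].
#' @param path Destination CSV path.
#' @return `features`, invisibly.
#' @export
write_lead_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(features)
}
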