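# Orchestration: simulate/read -> gap-fill -> binarize -> features ->
# five-step recipe per region x lead -> field significance and summaries.

#' Configuration of a full pipeline run
#'
#' Collects the file paths (or in-memory tables) and the method defaults:
#' 70/30 train/test split, 1000 bootstrap iterations, skill gates
#' AUC > 0.7 and p < 0.1, detrending at p <= 0.1, and the >20-year region
#' filter.
#'
#' @param index_file,regional_file,national_file,area_file CSV paths for
#'   the four input tables; may be omitted when tables are passed to
#'   [run_all()] directly.
#' @param leads Lead times to evaluate, a non-empty subset of 1:6.
#' @param train_fraction Training fraction (default 0.70).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param auc_gate,p_gate Skill gates (defaults 0.7 and 0.1).
#' @param trend_alpha Detrending significance level (default 0.1).
#' @param min_years Exclusive minimum labelled years per region
#'   (default 20).
#' @param null_method Bootstrap null, `"bootstrap"` or `"permutation"`.
#' @param seed Master seed; per-(region, lead) streams are derived from it
#'   and do not depend on execution order.
#' @param out_dir Optional directory where result CSVs are written.
#' @return A validated `run_config` list.
#' @export
run_config <- function(index_file = NULL, regional_file = NULL,
                       national_file = NULL, area_file = NULL,
                       leads = 1:6, train_fraction = 0.7, n_boot = 1000,
                       auc_gate = 0.7, p_gate = 0.1, trend_alpha = 0.1,
                       min_years = 20, null_method = "bootstrap",
                       seed = 1, out_dir = NULL) {
  if (length(leads) == 0) fc_stop("`leads` must be non-empty",
                                  "invalid_argument")
  if (!all(leads %in% 1:6)) fc_stop("`leads` must be within 1..6",
                                    "invalid_argument")
  for (g in c(auc_gate, p_gate, trend_alpha, train_fraction)) {
    if (!is.numeric(g) || g <= 0 || g >= 1) {
      fc_stop("gates and fractions must lie in (0, 1)", "invalid_argument")
    }
  }
  structure(list(
    index_file = index_file, regional_file = regional_file,
    national_file = national_file, area_file = area_file,
    leads = sort(unique(as.integer(leads))),
    train_fraction = train_fraction, n_boot = as.integer(n_boot),
    auc_gate = auc_gate, p_gate = p_gate, trend_alpha = trend_alpha,
    min_years = as.integer(min_years), null_method = null_method,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full forecasting pipeline
#'
#' Reads (or accepts) the four input tables, gap-fills regional production
#' from national totals, binarizes each region into high/low years,
#' computes 3-month lead-time index features, and runs the five-step
#' validation recipe for every region x lead with enough overlapping
#' years. Per-region failures are logged and skipped; they never abort the
#' run. Per lead, binomial field significance is computed over the
#' evaluated regions, and an overlay summary counts regions significant at
#' one or more leads.
#'
#' @param config A [run_config()].
#' @param data Optional list with tibbles `indices`, `regional`,
#'   `national`, `areas`, bypassing the file readers (e.g. the output of
#'   [simulate_scenario()]).
#' @param quiet Suppress progress messages.
#' @return A list with tibbles `results` (one row per evaluated
#'   region x lead), `field` (per-lead field significance), `overlay`
#'   (regions significant at >= 1 lead), `excluded` (regions dropped by the
#'   indicator filter), `skipped` (region x lead failures) and `fill_log`.
#'   Written as CSVs under `config$out_dir` when set.
#' @export
run_all <- function(config, data = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(data)) {
    indices <- read_climate_indices(config$index_file)
    regional <- read_regional_production(config$regional_file)
    national <- read_national_production(config$national_file)
    areas <- read_harvest_areas(config$area_file)
  } else {
    indices <- validate_climate_indices(data$indices)
    regional <- data$regional
    national <- data$national
    areas <- data$areas
  }

  filled <- fill_production(regional, national, areas)
  say("gap-filling: %d filled, %d zero-filled, %d left missing",
      sum(filled$data$fill_flag == "filled"),
      sum(filled$data$fill_flag == "zero-filled"),
      sum(filled$data$fill_flag == "left-missing"))

  region_ids <- unique(filled$data$region_id)
  indicators <- list()
  excluded <- list()
  for (rid in region_ids) {
    ser <- filled$data[filled$data$region_id == rid, c("year", "production")]
    ind <- make_indicator(ser, region_id = rid,
                          trend_alpha = config$trend_alpha,
                          min_years = config$min_years)
    if (ind$ok) {
      indicators[[rid]] <- ind
    } else {
      excluded[[length(excluded) + 1]] <- tibble::tibble(
        region_id = rid, reason = ind$reason, n_years = ind$n_years)
    }
  }
  excluded <- if (length(excluded) > 0) dplyr::bind_rows(excluded) else
    tibble::tibble(region_id = character(), reason = character(),
                   n_years = integer())
  say("indicator filter: %d region(s) kept, %d excluded",
      length(indicators), nrow(excluded))

  features_by_lead <- lapply(config$leads, function(ld) {
    compute_lead_features(indices, ld, quiet = quiet)
  })
  names(features_by_lead) <- as.character(config$leads)

  rows <- list()
  skipped <- list()
  for (ld in config$leads) {
    feats <- features_by_lead[[as.character(ld)]]
    feat_cols <- setdiff(names(feats), "year")
    for (rid in names(indicators)) {
      ind <- indicators[[rid]]
      common <- intersect(feats$year, ind$data$year)
      if (length(common) <= config$min_years) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          region_id = rid, lead = ld, reason = "insufficient-overlap",
          detail = sprintf("%d common year(s)", length(common)))
        next
      }
      f <- feats[match(common, feats$year), feat_cols, drop = FALSE]
      lab <- ind$data$label[match(common, ind$data$year)]
      res <- tryCatch(
        evaluate_region(f, lab,
                        train_fraction = config$train_fraction,
                        n_boot = config$n_boot,
                        auc_gate = config$auc_gate, p_gate = config$p_gate,
                        seed = derive_seed(config$seed,
                                           paste(rid, ld, sep = "|")),
                        null_method = config$null_method,
                        region_id = rid, lead = ld),
        frugalcast_error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          region_id = rid, lead = ld, reason = class(res)[1],
          detail = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        region_id = rid, lead = ld, n_years = res$n,
        pruning = res$pruning, auc = res$auc, bacc = res$bacc,
        hr = res$stats$HR, cr = res$stats$CR, far = res$stats$FAR,
        ms = res$stats$MS, ppv = res$stats$PPV, npv = res$stats$NPV,
        p_boot = res$p_boot, significant = res$significant,
        cues_used = paste(res$final_model$cues$feature, collapse = ";"))
    }
    say("lead %d: evaluated %d region(s)", ld,
        sum(vapply(rows, function(r) r$lead[1] == ld, logical(1))))
  }
  results <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(region_id = character(), lead = integer(),
                   n_years = integer(), pruning = integer(), auc = double(),
                   bacc = double(), hr = double(), cr = double(),
                   far = double(), ms = double(), ppv = double(),
                   npv = double(), p_boot = double(), significant = logical(),
                   cues_used = character())
  skipped <- if (length(skipped) > 0) dplyr::bind_rows(skipped) else
    tibble::tibble(region_id = character(), lead = integer(),
                   reason = character(), detail = character())

  field <- results |>
    dplyr::group_by(lead) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     n_significant = sum(significant, na.rm = TRUE),
                     .groups = "drop")
  field$alpha_local <- config$p_gate
  field$p_field <- mapply(field_significance, field$n_tests,
                          field$n_significant,
                          MoreArgs = list(alpha_local = config$p_gate))

  overlay <- results |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(n_leads_significant = sum(significant, na.rm = TRUE),
                     any_significant = any(significant %in% TRUE),
                     best_auc = max(auc), .groups = "drop")
  say("overlay: %d of %d region(s) significant at >= 1 lead",
      sum(overlay$any_significant), nrow(overlay))

  out <- list(results = results, field = field, overlay = overlay,
              excluded = excluded, skipped = skipped,
              fill_log = filled$log, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(config$out_dir, "results.csv"))
    readr::write_csv(field, file.path(config$out_dir,
                                      "field_significance.csv"))
    readr::write_csv(overlay, file.path(config$out_dir, "overlay.csv"))
    readr::write_csv(excluded, file.path(config$out_dir,
                                         "excluded_regions.csv"))
    readr::write_csv(filled$log, file.path(config$out_dir, "fill_log.csv"))
  }
  out
}
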