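# Train/test validation of FFT models, pruning selection, bootstrap
# significance per region, and binomial field significance across regions.

#' Specification of a train/test split
#'
#' @param train_fraction Fraction of rows used for training (default 0.70).
#' @param seed Integer seed making the split reproducible.
#' @param stratified Stratify by label so both classes appear on both sides
#'   whenever possible (default TRUE).
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1, stratified = TRUE) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      is.na(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    fc_stop("`train_fraction` must be in (0, 1)", "invalid_argument")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# largest-remainder allocation of `total` across groups of size `sizes`
allocate_proportional <- function(sizes, total) {
  q <- sizes * total / sum(sizes)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Reproducible (stratified) train/test split
#'
#' Splits row indices into train and test sets. Under stratification the
#' train quota is allocated across the two classes by largest remainder,
#' and clamped so every class keeps at least one row on each side. The same
#' seed always yields the same split.
#'
#' @param labels `"low"`/`"high"` labels, one per row.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  is_low <- as_is_low(labels)
  n <- length(is_low)
  idx_by_class <- list(low = which(is_low), high = which(!is_low))
  sizes <- lengths(idx_by_class)
  if (any(sizes < 2)) {
    fc_stop("each class needs at least 2 rows to split", "split_infeasible")
  }
  n_train <- round(spec$train_fraction * n)
  n_train <- min(max(n_train, 2), n - 2)
  take <- if (spec$stratified) {
    tk <- allocate_proportional(sizes, n_train)
    # keep >= 1 row of each class on each side
    tk <- pmin(pmax(tk, 1), sizes - 1)
    # restore the total within the clamped bounds
    delta <- n_train - sum(tk)
    for (j in seq_along(tk)) {
      if (delta == 0) break
      room <- if (delta > 0) sizes[j] - 1 - tk[j] else tk[j] - 1
      adj <- sign(delta) * min(abs(delta), room)
      tk[j] <- tk[j] + adj
      delta <- delta - adj
    }
    tk
  } else {
    NULL
  }
  with_seed(spec$seed, {
    if (spec$stratified) {
      train <- sort(unlist(lapply(seq_along(idx_by_class), function(j) {
        sample(idx_by_class[[j]], take[j])
      }), use.names = FALSE))
    } else {
      train <- sort(sample.int(n, n_train))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Select the pruning parameter (tree size) by train/test validation
#'
#' For each candidate maximum number of cues, fits an FFT fan on the
#' training rows, selects the best tree by training balanced accuracy, and
#' scores it on the test rows. Returns the candidate with the highest test
#' balanced accuracy; ties go to the smaller tree.
#'
#' @param features Data frame of numeric features.
#' @param labels `"low"`/`"high"` labels, one per row.
#' @param spec A [split_spec()]; ignored when `split` is given.
#' @param levels_grid Candidate maximum tree sizes (default 1:5).
#' @param split Optional precomputed split from [stratified_split()].
#' @return List with `pruning` (chosen size), `test_bacc`, and `per_level`,
#'   a tibble of test balanced accuracy per candidate.
#' @export
select_pruning <- function(features, labels, spec = split_spec(),
                           levels_grid = 1:5, split = NULL) {
  sp <- split %||% stratified_split(labels, spec)
  features <- as.data.frame(features)
  bacc <- vapply(levels_grid, function(L) {
    tryCatch({
      fan <- fft_build_fan(features[sp$train, , drop = FALSE],
                           labels[sp$train], max_levels = L)
      tree <- fft_select(fan, features[sp$train, , drop = FALSE],
                         labels[sp$train])
      pred <- fft_predict(tree, features[sp$test, , drop = FALSE])
      class_stats(confusion_counts(labels[sp$test], pred))$BACC
    }, frugalcast_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(bacc))) {
    fc_stop("no candidate tree size could be fitted", "region_unfittable")
  }
  best <- order(-bacc, levels_grid, na.last = TRUE)[1]
  list(pruning = as.integer(levels_grid[best]), test_bacc = bacc[best],
       per_level = tibble::tibble(max_levels = as.integer(levels_grid),
                                  test_bacc = bacc))
}

#' Bootstrap p-value for a region's test AUC
#'
#' Builds the null distribution of fan AUC by resampling the label vector
#' (with replacement by default, permutation optionally), which severs the
#' climate-production link while keeping the features and the train/test
#' partition fixed. Each replicate refits the fan on the training rows at
#' the chosen pruning and scores fan AUC on the test rows. The p-value uses
#' the add-one estimator `(1 + #\{AUC_null >= AUC_obs\}) / (n_iter + 1)`,
#' so it is never smaller than `1/(n_iter + 1)`.
#'
#' @inheritParams select_pruning
#' @param split The observed train/test split (list with `train`, `test`).
#' @param pruning Maximum tree size used for the observed model.
#' @param observed_auc Test-set fan AUC of the observed model.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param method `"bootstrap"` (labels resampled with replacement) or
#'   `"permutation"`.
#' @param max_retry Redraw cap per iteration when a resample leaves one
#'   side of the split single-class.
#' @return The p-value, with the null AUC draws attached as attribute
#'   `"null_auc"`.
#' @export
bootstrap_p <- function(features, labels, split, pruning, observed_auc,
                        n_iter = 1000, seed = 1,
                        method = c("bootstrap", "permutation"),
                        max_retry = 100) {
  method <- match.arg(method)
  features <- as.data.frame(features)
  is_low <- as_is_low(labels)
  lab <- ifelse(is_low, "low", "high")
  tr <- split$train
  te <- split$test
  f_tr <- features[tr, , drop = FALSE]
  f_te <- features[te, , drop = FALSE]
  aucs <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      for (r in seq_len(max_retry)) {
        lab_null <- if (method == "bootstrap") {
          sample(lab, replace = TRUE)
        } else {
          sample(lab)
        }
        ok <- length(unique(lab_null[tr])) == 2 &&
          length(unique(lab_null[te])) == 2
        if (ok) break
        if (r == max_retry) {
          fc_stop("degenerate resample: retry cap exhausted",
                  "degenerate_resample")
        }
      }
      fan <- fft_build_fan(f_tr, lab_null[tr], max_levels = pruning)
      fan_auc(fan, f_te, lab_null[te])
    }, numeric(1))
  })
  p <- (1 + sum(aucs >= observed_auc)) / (n_iter + 1)
  attr(p, "null_auc") <- aucs
  p
}

#' Binomial field significance
#'
#' Tests whether the number of locally significant regions exceeds what
#' chance would produce: with `n_tests` independent tests at local level
#' `alpha_local`, the field p-value is the exact upper binomial tail
#' `P(X >= n_significant)` for `X ~ Binomial(n_tests, alpha_local)`.
#'
#' @param n_tests Number of regional tests performed.
#' @param n_significant Number found locally significant.
#' @param alpha_local Local significance level (default 0.1).
#' @return The field p-value.
#' @export
field_significance <- function(n_tests, n_significant, alpha_local = 0.1) {
  if (n_tests < 0 || n_significant < 0 || n_significant > n_tests) {
    fc_stop("need 0 <= n_significant <= n_tests", "invalid_argument")
  }
  stats::pbinom(n_significant - 1, n_tests, alpha_local, lower.tail = FALSE)
}

#' Refit the final tree on all data
#'
#' After validation, the training and test samples are recombined and the
#' fan is refitted at the selected pruning; the best tree by balanced
#' accuracy on the full data is the final, reportable model.
#'
#' @inheritParams select_pruning
#' @param pruning Selected maximum tree size.
#' @return An `fft_tree` with attribute `cues_used`, the ordered feature
#'   names of its cues.
#' @export
finalize_fft <- function(features, labels, pruning) {
  fan <- fft_build_fan(features, labels, max_levels = pruning)
  tree <- fft_select(fan, features, labels)
  attr(tree, "cues_used") <- tree$cues$feature
  tree
}

#' Evaluate one region at one lead time (the five-step recipe)
#'
#' Runs the full validation recipe for one region x lead: (1) split the
#' years 70/30 (stratified); (2) select the pruning parameter maximizing
#' test balanced accuracy; (3) compute the fan AUC on the test rows;
#' (4) assess its significance by label bootstrap; (5) compute standard
#' classification statistics of the selected tree on the test rows. The
#' final model is then refitted on the recombined data at the selected
#' pruning. A region-lead is flagged significant when test AUC exceeds
#' `auc_gate` and the bootstrap p-value is below `p_gate`.
#'
#' @param features Data frame of lead-time index features (rows = years).
#' @param labels `"low"`/`"high"` production labels, one per row.
#' @param train_fraction Training fraction (default 0.70).
#' @param n_boot Bootstrap iterations (default 1000); 0 skips the
#'   bootstrap and leaves `p_boot` as `NA`.
#' @param auc_gate,p_gate Skill gates: significant iff `auc > auc_gate`
#'   and `p_boot < p_gate` (defaults 0.7 and 0.1).
#' @param seed Integer seed; split and bootstrap streams are derived from
#'   it deterministically.
#' @param levels_grid Candidate tree sizes (default 1:5).
#' @param null_method Passed to [bootstrap_p()].
#' @param region_id,lead Optional identifiers carried into the result.
#' @return An `evaluation_result` list: `pruning`, `auc`, `bacc`, `stats`
#'   (test-set [class_stats()]), `p_boot`, `significant`, `final_model`,
#'   plus the split and sample size.
#' @export
evaluate_region <- function(features, labels, train_fraction = 0.7,
                            n_boot = 1000, auc_gate = 0.7, p_gate = 0.1,
                            seed = 1, levels_grid = 1:5,
                            null_method = "bootstrap",
                            region_id = NULL, lead = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) != length(labels)) {
    fc_stop("features and labels differ in length", "invalid_argument")
  }
  spec <- split_spec(train_fraction, seed = derive_seed(seed, "split"))
  sp <- stratified_split(labels, spec)
  sel <- select_pruning(features, labels, spec, levels_grid, split = sp)

  f_tr <- features[sp$train, , drop = FALSE]
  f_te <- features[sp$test, , drop = FALSE]
  fan <- fft_build_fan(f_tr, labels[sp$train], max_levels = sel$pruning)
  tree <- fft_select(fan, f_tr, labels[sp$train])
  pred <- fft_predict(tree, f_te)
  stats <- class_stats(confusion_counts(labels[sp$test], pred))
  auc <- fan_auc(fan, f_te, labels[sp$test])

  p_boot <- if (n_boot > 0) {
    as.numeric(bootstrap_p(features, labels, sp, sel$pruning, auc,
                           n_iter = n_boot,
                           seed = derive_seed(seed, "bootstrap"),
                           method = null_method))
  } else {
    NA_real_
  }
  significant <- if (is.na(p_boot)) NA else (auc > auc_gate && p_boot < p_gate)
  final <- finalize_fft(features, labels, sel$pruning)

  structure(list(
    region_id = region_id, lead = lead, n = nrow(features),
    pruning = sel$pruning, auc = auc, bacc = stats$BACC, stats = stats,
    p_boot = p_boot, significant = significant, final_model = final,
    split = sp, per_level = sel$per_level
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> %s lead %s: n %d, pruning %d, AUC %.3f, BACC %.3f, p_boot %s, %s\n",
    x$region_id %||% "<region>", x$lead %||% "?", x$n, x$pruning,
    x$auc, x$bacc,
    if (is.na(x$p_boot)) "NA" else sprintf("%.4f", x$p_boot),
    if (isTRUE(x$significant)) "significant" else "not significant"))
  cat("  final cues:", paste(x$final_model$cues$feature, collapse = " > "),
      "\n")
  invisible(x)
}
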