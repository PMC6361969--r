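# Fast-and-frugal tree learner (ifan construction), written from scratch.
#
# A fast-and-frugal tree (FFT) classifies a case as "low" or "high"
# production by scanning an ordered list of cues; every non-final cue has a
# single exit (an immediate classification on one side of its threshold)
# and the final cue exits both ways. Construction follows ifan: threshold
# each cue to maximize its standalone balanced accuracy, rank cues by that
# accuracy, enumerate all single-exit structures over the retained cues
# (the "fan"), and keep the tree with the highest training balanced
# accuracy. The fan's (FAR, HR) points trace the ROC curve used for AUC.

#' Balanced-accuracy-optimal threshold for one cue
#'
#' Scans every decision-equivalent threshold (midpoints between consecutive
#' sorted distinct values) in both directions and returns the cut that
#' maximizes standalone balanced accuracy, `(HR + CR) / 2`, where `HR` is
#' the rate of correctly classified low years and `CR` of high years. The
#' cue's `direction` is the side of the threshold that signals `"low"`.
#' Ties are broken towards the smaller threshold, then direction `"<="`.
#'
#' @param x Numeric feature values.
#' @param labels `"low"`/`"high"` labels (or logical, TRUE = low).
#' @param feature Optional feature name stored on the cue.
#' @return An `fft_cue`: list with `feature`, `threshold`, `direction`
#'   (`"<="` or `">"`, pointing to the low decision) and `bacc`, the
#'   standalone balanced accuracy in \[0, 1\]. A constant feature yields its
#'   single value as threshold and `bacc = 0.5`.
#' @export
fft_best_threshold <- function(x, labels, feature = NULL) {
  is_low <- as_is_low(labels)
  if (length(x) != length(is_low)) {
    fc_stop("feature and label lengths differ", "invalid_argument")
  }
  if (any(!is.finite(x))) fc_stop("feature values must be finite",
                                  "invalid_argument")
  n_low <- sum(is_low)
  n_high <- sum(!is_low)
  if (n_low == 0 || n_high == 0) {
    fc_stop("both classes must be present to threshold a cue",
            "undefined_cue")
  }
  o <- order(x)
  xo <- x[o]
  lo <- is_low[o]
  last <- which(diff(xo) > 0) # last position of each distinct value but the max
  if (length(last) == 0) {
    return(new_cue(feature, xo[1], "<=", 0.5))
  }
  mids <- (xo[last] + xo[last + 1]) / 2
  cum_low <- cumsum(lo)[last]
  cum_high <- cumsum(!lo)[last]
  # direction "<=": classify low when x <= t
  bacc_le <- (cum_low / n_low + (n_high - cum_high) / n_high) / 2
  bacc_gt <- 1 - bacc_le
  bacc <- c(bacc_le, bacc_gt)
  thr <- c(mids, mids)
  dir_rank <- rep(1:2, each = length(mids)) # "<=" preferred on ties
  best <- order(-bacc, thr, dir_rank)[1]
  new_cue(feature, thr[best], c("<=", ">")[dir_rank[best]], bacc[best])
}

new_cue <- function(feature, threshold, direction, bacc) {
  structure(list(feature = feature, threshold = threshold,
                 direction = direction, bacc = bacc),
            class = "fft_cue")
}

#' Rank all cues by standalone balanced accuracy
#'
#' Applies [fft_best_threshold()] to every feature column and orders the
#' cues by decreasing standalone balanced accuracy; ties keep the order in
#' which features appear in `features` (deterministic, no randomness).
#'
#' @param features Data frame or matrix of numeric features with names.
#' @inheritParams fft_best_threshold
#' @return A data frame with columns `feature`, `direction`, `threshold`,
#'   `bacc`, one row per cue, best first.
#' @export
fft_rank_cues <- function(features, labels) {
  features <- as.data.frame(features)
  if (ncol(features) == 0) fc_stop("no usable cue", "empty_fan")
  cues <- lapply(names(features), function(nm) {
    cue <- fft_best_threshold(features[[nm]], labels, feature = nm)
    data.frame(feature = nm, direction = cue$direction,
               threshold = cue$threshold, bacc = cue$bacc,
               stringsAsFactors = FALSE)
  })
  cues <- do.call(rbind, cues)
  cues[order(-cues$bacc, seq_len(nrow(cues))), , drop = FALSE]
}

#' Build the fan of fast-and-frugal trees
#'
#' Ranks cues, keeps the best `max_levels` (at most five), and enumerates
#' every exit structure: each non-final node exits either `"low"` or
#' `"high"`, the final node exits both ways, giving `2^(k-1)` trees for `k`
#' retained cues. All trees share cue order and thresholds; they differ
#' only in exits.
#'
#' @inheritParams fft_rank_cues
#' @param max_levels Maximum number of cues retained, 1--5.
#' @return An `fft_fan`: list with `cues` (ranked cue table) and `exits`
#'   (character matrix, one row per tree; final column `"both"`). Trees are
#'   materialized with [fan_trees()].
#' @export
fft_build_fan <- function(features, labels, max_levels = 5) {
  if (!is.numeric(max_levels) || length(max_levels) != 1L ||
      is.na(max_levels) || max_levels < 1 || max_levels > 5 ||
      max_levels != round(max_levels)) {
    fc_stop("`max_levels` must be a single integer between 1 and 5",
            "invalid_argument")
  }
  is_low <- as_is_low(labels)
  if (sum(is_low) == 0 || sum(!is_low) == 0) {
    fc_stop("both classes must be present to build a fan", "undefined_cue")
  }
  ranked <- fft_rank_cues(features, is_low)
  k <- min(as.integer(max_levels), nrow(ranked))
  cues <- ranked[seq_len(k), , drop = FALSE]
  rownames(cues) <- NULL
  exits <- if (k == 1) {
    matrix("both", 1, 1)
  } else {
    g <- expand.grid(rep(list(c("high", "low")), k - 1),
                     stringsAsFactors = FALSE)
    unname(cbind(as.matrix(g), "both"))
  }
  structure(list(cues = cues, exits = exits), class = "fft_fan")
}

#' @export
print.fft_fan <- function(x, ...) {
  cat(sprintf("<fft_fan> %d tree(s) over %d cue(s): %s\n",
              nrow(x$exits), nrow(x$cues),
              paste(x$cues$feature, collapse = ", ")))
  invisible(x)
}

#' Number of trees in a fan
#' @param fan An `fft_fan`.
#' @return Integer count of trees.
#' @export
fan_size <- function(fan) nrow(fan$exits)

#' Materialize the trees of a fan
#' @param fan An `fft_fan`.
#' @return A list of `fft_tree` objects in fan order.
#' @export
fan_trees <- function(fan) {
  lapply(seq_len(nrow(fan$exits)), function(i) {
    new_tree(fan$cues, fan$exits[i, ])
  })
}

new_tree <- function(cues, exits) {
  structure(list(cues = cues, exits = as.character(exits)),
            class = "fft_tree")
}

#' @export
print.fft_tree <- function(x, ...) {
  cat(sprintf("<fft_tree> %d cue(s)\n", nrow(x$cues)))
  for (j in seq_len(nrow(x$cues))) {
    cond <- sprintf("%s %s %.4g", x$cues$feature[j], x$cues$direction[j],
                    x$cues$threshold[j])
    if (x$exits[j] == "both") {
      cat(sprintf("  %d. if %s -> LOW else HIGH\n", j, cond))
    } else if (x$exits[j] == "low") {
      cat(sprintf("  %d. if %s -> LOW else next\n", j, cond))
    } else {
      cat(sprintf("  %d. if not (%s) -> HIGH else next\n", j, cond))
    }
  }
  invisible(x)
}

# n x k logical matrix; TRUE where cue j's direction condition holds
# (i.e. the cue, taken alone, indicates low production)
cue_conditions <- function(cues, features) {
  if (is.matrix(features)) features <- as.data.frame(features)
  miss <- setdiff(cues$feature, names(features))
  if (length(miss) > 0) {
    fc_stop(sprintf("feature(s) missing from data: %s",
                    paste(miss, collapse = ", ")),
            "prediction_undefined")
  }
  n <- nrow(features)
  cond <- matrix(FALSE, n, nrow(cues))
  for (j in seq_len(nrow(cues))) {
    v <- features[[cues$feature[j]]]
    if (anyNA(v)) {
      fc_stop(sprintf("missing value in feature '%s'", cues$feature[j]),
              "prediction_undefined")
    }
    cond[, j] <- if (cues$direction[j] == "<=") v <= cues$threshold[j]
                 else v > cues$threshold[j]
  }
  cond
}

# Walk one exit structure over a precomputed condition matrix.
# Returns pred_low (logical) and depth (node index deciding each row).
predict_exits <- function(cond, exits) {
  n <- nrow(cond)
  k <- length(exits)
  pred_low <- logical(n)
  depth <- integer(n)
  undecided <- rep(TRUE, n)
  for (j in seq_len(k)) {
    if (exits[j] == "low") {
      sel <- undecided & cond[, j]
      pred_low[sel] <- TRUE
    } else if (exits[j] == "high") {
      sel <- undecided & !cond[, j]
      pred_low[sel] <- FALSE
    } else { # both: final node
      sel <- undecided
      pred_low[sel] <- cond[sel, j]
    }
    depth[sel] <- j
    undecided[sel] <- FALSE
  }
  list(pred_low = pred_low, depth = depth)
}

#' Predict with a fast-and-frugal tree
#'
#' Cues are evaluated in order; the first triggered exit decides, and the
#' final cue always decides. The tree is non-compensatory: once a row
#' exits, the values of later cues cannot change its classification.
#'
#' @param model An `fft_tree`.
#' @param features Data frame (or matrix with column names) holding all cue
#'   features; a missing value in a needed feature is an error of class
#'   `prediction_undefined`.
#' @return Character vector of `"low"`/`"high"`, with the deciding node
#'   index attached as attribute `"depth"`.
#' @export
fft_predict <- function(model, features) {
  cond <- cue_conditions(model$cues, features)
  res <- predict_exits(cond, model$exits)
  structure(ifelse(res$pred_low, "low", "high"), depth = res$depth)
}

#' Confusion counts for binary high/low predictions
#'
#' Counts follow the low-production-as-signal convention: `TL` true lows,
#' `TH` true highs, `FL` false lows (high years predicted low), `FH` false
#' highs (low years predicted high); `LP = TL + FH` observed lows and
#' `HP = TH + FL` observed highs.
#'
#' @param labels Observed `"low"`/`"high"` labels.
#' @param predictions Predicted labels of the same length.
#' @return A `confusion_counts` list with `TL`, `TH`, `FL`, `FH`, `LP`,
#'   `HP`.
#' @export
confusion_counts <- function(labels, predictions) {
  obs <- as_is_low(labels)
  pred <- as_is_low(predictions)
  if (length(obs) != length(pred)) {
    fc_stop("labels and predictions differ in length", "invalid_argument")
  }
  structure(list(
    TL = sum(obs & pred), TH = sum(!obs & !pred),
    FL = sum(!obs & pred), FH = sum(obs & !pred),
    LP = sum(obs), HP = sum(!obs)
  ), class = "confusion_counts")
}

#' Standard classification statistics for high/low forecasts
#'
#' Computes the statistics used to judge a forecast of low-production
#' events: hit rate `HR = TL/LP`, correct rejection rate `CR = TH/HP`,
#' false alarm rate `FAR = 1 - CR`, miss rate `MS = 1 - HR`, positive and
#' negative predictive value `PPV = HR/(HR + FAR)` and `NPV = CR/(CR +
#' MS)` (NA when their denominator is zero), and balanced accuracy
#' `BACC = 0.5 HR + 0.5 CR`. All are proportions in \[0, 1\].
#'
#' @param counts A `confusion_counts` object.
#' @return A `class_stats` list with `HR`, `CR`, `FAR`, `MS`, `PPV`,
#'   `NPV`, `BACC`.
#' @export
class_stats <- function(counts) {
  if (counts$LP == 0 || counts$HP == 0) {
    fc_stop("both observed classes are required for classification stats",
            "stats_undefined")
  }
  hr <- counts$TL / counts$LP
  cr <- counts$TH / counts$HP
  far <- 1 - cr
  ms <- 1 - hr
  structure(list(
    HR = hr, CR = cr, FAR = far, MS = ms,
    PPV = if (hr + far > 0) hr / (hr + far) else NA_real_,
    NPV = if (cr + ms > 0) cr / (cr + ms) else NA_real_,
    BACC = 0.5 * hr + 0.5 * cr
  ), class = "class_stats")
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf(
    "<class_stats> HR %.1f%%  CR %.1f%%  FAR %.1f%%  MS %.1f%%  PPV %.1f%%  NPV %.1f%%  BACC %.1f%%\n",
    100 * x$HR, 100 * x$CR, 100 * x$FAR, 100 * x$MS,
    100 * (x$PPV %||% NA), 100 * (x$NPV %||% NA), 100 * x$BACC))
  invisible(x)
}

#' ROC points of a fan
#'
#' Scores every tree of the fan on the supplied data and returns its
#' `(FAR, HR)` operating point. Because fan members share cues and differ
#' only in how liberally they exit towards "low", the points sweep out the
#' ROC curve of the method.
#'
#' @param fan An `fft_fan`.
#' @inheritParams fft_rank_cues
#' @return A data frame with columns `far` and `hr`, one row per tree in
#'   fan order.
#' @export
fan_roc_points <- function(fan, features, labels) {
  is_low <- as_is_low(labels)
  n_low <- sum(is_low)
  n_high <- sum(!is_low)
  if (n_low == 0 || n_high == 0) {
    fc_stop("both classes are required for ROC points", "stats_undefined")
  }
  cond <- cue_conditions(fan$cues, features)
  pts <- t(vapply(seq_len(nrow(fan$exits)), function(i) {
    pred_low <- predict_exits(cond, fan$exits[i, ])$pred_low
    c(far = sum(pred_low & !is_low) / n_high,
      hr = sum(pred_low & is_low) / n_low)
  }, numeric(2)))
  as.data.frame(pts)
}

#' Fan AUC by the trapezoidal rule
#'
#' The fan's `(FAR, HR)` points, augmented with the `(0, 0)` and `(1, 1)`
#' anchors, are sorted by FAR (then HR), deduplicated, and integrated with
#' the trapezoidal rule. A perfect tree in the fan gives 1.0; label-
#' independent predictions give about 0.5.
#'
#' @inheritParams fan_roc_points
#' @return AUC in \[0, 1\].
#' @export
fan_auc <- function(fan, features, labels) {
  pts <- fan_roc_points(fan, features, labels)
  pts <- rbind(data.frame(far = 0, hr = 0), pts, data.frame(far = 1, hr = 1))
  pts <- unique(pts[order(pts$far, pts$hr), , drop = FALSE])
  x <- pts$far
  y <- pts$hr
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Select the best tree from a fan
#'
#' Returns the fan member with the highest balanced accuracy on the
#' supplied (training) data. Ties are broken towards fewer effective
#' levels (the deepest node that actually decides any row) and then fan
#' order, so selection is deterministic.
#'
#' @inheritParams fan_roc_points
#' @return An `fft_tree` with attributes `train_bacc` and
#'   `effective_levels`.
#' @export
fft_select <- function(fan, features, labels) {
  if (nrow(fan$exits) == 0) fc_stop("empty fan", "empty_fan")
  is_low <- as_is_low(labels)
  if (sum(is_low) == 0 || sum(!is_low) == 0) {
    fc_stop("both classes are required to select a tree", "stats_undefined")
  }
  cond <- cue_conditions(fan$cues, features)
  n_low <- sum(is_low)
  n_high <- sum(!is_low)
  n_tree <- nrow(fan$exits)
  bacc <- numeric(n_tree)
  eff <- integer(n_tree)
  for (i in seq_len(n_tree)) {
    res <- predict_exits(cond, fan$exits[i, ])
    hr <- sum(res$pred_low & is_low) / n_low
    cr <- sum(!res$pred_low & !is_low) / n_high
    bacc[i] <- (hr + cr) / 2
    eff[i] <- max(res$depth)
  }
  best <- order(-bacc, eff, seq_len(n_tree))[1]
  tree <- new_tree(fan$cues, fan$exits[best, ])
  attr(tree, "train_bacc") <- bacc[best]
  attr(tree, "effective_levels") <- eff[best]
  attr(tree, "fan_bacc") <- bacc
  tree
}

#' Serialize a fast-and-frugal tree to readable text
#'
#' One cue per line: feature, direction, threshold (full precision) and
#' exit, tab-separated. The format round-trips through [read_fft()].
#'
#' @param model An `fft_tree`.
#' @param path Destination file.
#' @return `model`, invisibly.
#' @export
write_fft <- function(model, path) {
  lines <- c(
    "# fast-and-frugal tree (feature, direction-to-low, threshold, exit)",
    vapply(seq_len(nrow(model$cues)), function(j) {
      paste(model$cues$feature[j], model$cues$direction[j],
            format(model$cues$threshold[j], digits = 17),
            model$exits[j], sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(model)
}

#' @rdname write_fft
#' @return For `read_fft`, the deserialized `fft_tree`.
#' @export
read_fft <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) fc_stop("no cues in file", "schema_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    fc_stop("each cue line must have 4 tab-separated fields", "schema_error")
  }
  m <- do.call(rbind, parts)
  cues <- data.frame(feature = m[, 1], direction = m[, 2],
                     threshold = as.numeric(m[, 3]), bacc = NA_real_,
                     stringsAsFactors = FALSE)
  if (!all(cues$direction %in% c("<=", ">"))) {
    fc_stop("direction must be '<=' or '>'", "schema_error")
  }
  exits <- m[, 4]
  if (exits[length(exits)] != "both" ||
      !all(exits[-length(exits)] %in% c("low", "high"))) {
    fc_stop("exits must be low/high with a final 'both'", "schema_error")
  }
  new_tree(cues, exits)
}
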