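test_that("threshold selection maximizes standalone balanced accuracy", {
  cue <- fft_best_threshold(c(1, 2, 3, 4), c("low", "low", "high", "high"))
  expect_equal(cue$threshold, 2.5)
  expect_identical(cue$direction, "<=")
  expect_equal(cue$bacc, 1.0)

  # every arrangement of 2 low / 2 high over distinct values: BACC >= 0.5
  perms <- unique(combinat <- t(apply(
    expand.grid(rep(list(c("low", "high")), 4)), 1, as.character)))
  perms <- perms[rowSums(perms == "low") == 2, , drop = FALSE]
  expect_identical(nrow(perms), 6L)
  for (i in seq_len(nrow(perms))) {
    cue <- fft_best_threshold(c(1, 2, 3, 4), perms[i, ])
    expect_gte(cue$bacc, 0.5)
    expect_equal(cue$bacc, brute_best_bacc(c(1, 2, 3, 4), perms[i, ]))
  }

  # constant feature: no informative cut, BACC 0.5
  cue <- fft_best_threshold(rep(1.3, 6),
                            c("low", "low", "low", "high", "high", "high"))
  expect_equal(cue$bacc, 0.5)
  expect_equal(cue$threshold, 1.3)

  expect_error(fft_best_threshold(1:4, rep("low", 4)),
               class = "undefined_cue")
})

test_that("threshold selection matches brute force on random small cases", {
  set.seed(101)
  for (i in 1:200) {
    case <- random_cue_case(sample(4:12, 1), n_distinct = sample(3:12, 1))
    cue <- fft_best_threshold(case$x, case$labels)
    expect_equal(cue$bacc, brute_best_bacc(case$x, case$labels),
                 tolerance = 1e-12)
    # the returned cue reproduces its own claimed accuracy
    pred_low <- if (cue$direction == "<=") case$x <= cue$threshold else
      case$x > cue$threshold
    is_low <- case$labels == "low"
    hr <- sum(pred_low & is_low) / sum(is_low)
    cr <- sum(!pred_low & !is_low) / sum(!is_low)
    expect_equal((hr + cr) / 2, cue$bacc)
  }
})

test_that("the fan enumerates all exit structures over ranked cues", {
  set.seed(7)
  n <- 30
  lab <- rep(c("low", "high"), 15)
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n),
                  e = rnorm(n))
  for (k in 1:5) {
    fan <- fft_build_fan(X[, 1:k, drop = FALSE], lab, max_levels = 5)
    expect_identical(fan_size(fan), as.integer(2^(k - 1)))
    expect_identical(nrow(fan$cues), k)
  }
  fan <- fft_build_fan(X, lab, max_levels = 3)
  expect_identical(fan_size(fan), 4L)
  # cues are ranked by decreasing standalone accuracy
  expect_true(all(diff(fan$cues$bacc) <= 1e-12))
  # every tree ends with a both-ways exit and has single exits before it
  trees <- fan_trees(fan)
  for (tr in trees) {
    expect_identical(tr$exits[length(tr$exits)], "both")
    expect_true(all(tr$exits[-length(tr$exits)] %in% c("low", "high")))
  }
  expect_error(fft_build_fan(X, rep("low", n)), class = "undefined_cue")
})

test_that("a perfectly separating cue dominates the fan", {
  # two cues: `good` separates perfectly; `weak` (standalone BACC 0.75)
  # classifies the rows that fall through `good`'s low exit consistently,
  # so one fan member attains BACC 1
  lab <- rep(c("low", "high"), each = 10)
  X <- data.frame(good = c(seq(-4, -2, length.out = 10),
                           seq(2, 4, length.out = 10)),
                  weak = c(0:4, 15:19, 10:19))
  fan <- fft_build_fan(X, lab, max_levels = 2)
  expect_identical(fan$cues$feature[1], "good")
  expect_equal(fan$cues$bacc, c(1.0, 0.75))
  tree <- fft_select(fan, X, lab)
  expect_equal(attr(tree, "train_bacc"), 1.0)
  # best fan member reaches BACC 1 when every tree is scored by hand
  baccs <- vapply(fan_trees(fan), function(tr) {
    class_stats(confusion_counts(lab, fft_predict(tr, X)))$BACC
  }, numeric(1))
  expect_equal(max(baccs), 1.0)
  # selection invariant: chosen training BACC >= every fan member's
  expect_true(all(attr(tree, "train_bacc") >= baccs - 1e-12))
  # the same selection score recomputed independently
  expect_equal(attr(tree, "train_bacc"), max(baccs))
})

test_that("tree selection breaks ties deterministically", {
  # single-member fan returns that tree
  lab <- rep(c("low", "high"), 5)
  X <- data.frame(a = 1:10)
  fan <- fft_build_fan(X, lab, max_levels = 1)
  t1 <- fft_select(fan, X, lab)
  expect_identical(t1$exits, "both")
  # all-equal accuracy: the shallower tree wins (fewer effective levels)
  Xc <- data.frame(a = rep(1, 10), b = rep(2, 10))
  fanc <- fft_build_fan(Xc, lab, max_levels = 2)
  tc <- fft_select(fanc, Xc, lab)
  expect_identical(attr(tc, "effective_levels"), 1L)
  expect_identical(tc$exits, c("low", "both"))
  # equal accuracy and equal depth: first member in fan order wins
  Xd <- data.frame(a = c(0, 1), b = c(0, 1))
  labd <- c("low", "high")
  fand <- fft_build_fan(Xd, labd, max_levels = 2)
  td <- fft_select(fand, Xd, labd)
  expect_identical(td$exits, fand$exits[1, ])
})

test_that("prediction is non-compensatory and fails loudly on missing cues", {
  cues <- data.frame(feature = c("a", "b", "c"),
                     direction = c("<=", ">", "<="),
                     threshold = c(2.5, 0, 1), bacc = NA)
  tree <- frugalcast:::new_tree(cues, c("low", "high", "both"))
  row <- data.frame(a = 1.0, b = 5, c = 9)
  expect_identical(as.character(fft_predict(tree, row)), "low")
  # first cue exits low for this row: later cues are irrelevant
  for (i in 1:10) {
    row2 <- data.frame(a = 1.0, b = rnorm(1, sd = 10), c = rnorm(1, sd = 10))
    expect_identical(as.character(fft_predict(tree, row2)), "low")
  }
  row3 <- data.frame(a = 3.0, b = -1, c = 0.5) # falls through to final node
  expect_identical(as.character(fft_predict(tree, row3)), "high")
  expect_identical(attr(fft_predict(tree, row3), "depth"), 2L)

  single <- frugalcast:::new_tree(cues[1, ], "both")
  expect_identical(as.character(fft_predict(single, data.frame(a = 1))),
                   "low")
  expect_identical(as.character(fft_predict(single, data.frame(a = 3))),
                   "high")
  expect_error(fft_predict(tree, data.frame(a = 1, b = NA, c = 1)),
               class = "prediction_undefined")
  expect_error(fft_predict(tree, data.frame(a = 1, b = 2)),
               class = "prediction_undefined")
})

test_that("classification statistics satisfy their defining identities", {
  counts <- structure(list(TL = 3, TH = 2, FL = 2, FH = 1, LP = 4, HP = 4),
                      class = "confusion_counts")
  s <- class_stats(counts)
  expect_equal(s$HR, 0.75)
  expect_equal(s$CR, 0.5)
  expect_equal(s$FAR, 0.5)
  expect_equal(s$BACC, 0.625)

  perfect <- confusion_counts(c("low", "low", "high"),
                              c("low", "low", "high"))
  sp <- class_stats(perfect)
  expect_equal(unlist(sp[c("HR", "CR", "BACC", "PPV", "NPV")]),
               c(HR = 1, CR = 1, BACC = 1, PPV = 1, NPV = 1))
  expect_equal(unlist(sp[c("FAR", "MS")]), c(FAR = 0, MS = 0))

  wrong <- class_stats(confusion_counts(c("low", "high"), c("high", "low")))
  expect_equal(wrong$BACC, 0)
  expect_equal(wrong$HR, 0)
  expect_equal(wrong$MS, 1)

  # identities on random confusions + label-swap symmetry
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    obs <- sample(c("low", "high"), n, replace = TRUE)
    pred <- sample(c("low", "high"), n, replace = TRUE)
    if (length(unique(obs)) < 2) next
    s <- class_stats(confusion_counts(obs, pred))
    expect_equal(s$HR + s$MS, 1)
    expect_equal(s$CR + s$FAR, 1)
    expect_equal(s$BACC, (s$HR + s$CR) / 2)
    if (!is.na(s$PPV)) expect_equal(s$PPV, s$HR / (s$HR + s$FAR))
    if (!is.na(s$NPV)) expect_equal(s$NPV, s$CR / (s$CR + s$MS))
    swap <- function(x) ifelse(x == "low", "high", "low")
    s2 <- class_stats(confusion_counts(swap(obs), swap(pred)))
    expect_equal(s2$HR, s$CR)
    expect_equal(s2$CR, s$HR)
    expect_equal(s2$BACC, s$BACC)
    if (!is.na(s$PPV) && !is.na(s2$NPV)) expect_equal(s2$NPV, s$PPV)
  }
  expect_error(class_stats(confusion_counts(rep("low", 3), rep("low", 3))),
               class = "stats_undefined")
})

test_that("fan AUC equals an independent trapezoid and hits the anchors", {
  # a fan whose cues separate perfectly yields AUC exactly 1
  lab <- rep(c("low", "high"), each = 12)
  X <- data.frame(f1 = c(1:12, 31:42), f2 = c(1:12, 31:42) * 2 + 1)
  fan <- fft_build_fan(X, lab, max_levels = 2)
  expect_identical(fan_auc(fan, X, lab), 1.0)

  # agreement with a second trapezoid implementation on noisy fans
  set.seed(21)
  for (i in 1:25) {
    n <- 40
    labn <- sample(rep(c("low", "high"), n / 2))
    Xn <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    fann <- fft_build_fan(Xn, labn, max_levels = 3)
    pts <- fan_roc_points(fann, Xn, labn)
    pts <- unique(rbind(data.frame(far = 0, hr = 0), pts,
                        data.frame(far = 1, hr = 1)))
    expect_equal(fan_auc(fann, Xn, labn),
                 trapezoid_area(pts$far, pts$hr), tolerance = 1e-12)
    expect_gte(fan_auc(fann, Xn, labn), 0)
    expect_lte(fan_auc(fann, Xn, labn), 1)
  }
})

test_that("tree serialization round-trips", {
  lab <- rep(c("low", "high"), each = 8)
  X <- data.frame(soi = rnorm(16), nao = c(rnorm(8, -1), rnorm(8, 1)),
                  ea = rnorm(16))
  fan <- fft_build_fan(X, lab, max_levels = 3)
  tree <- fft_select(fan, X, lab)
  tmp <- tempfile(fileext = ".fft")
  on.exit(unlink(tmp))
  write_fft(tree, tmp)
  back <- read_fft(tmp)
  expect_identical(back$cues$feature, tree$cues$feature)
  expect_identical(back$cues$direction, tree$cues$direction)
  expect_identical(back$cues$threshold, tree$cues$threshold)
  expect_identical(back$exits, tree$exits)
  expect_identical(as.character(fft_predict(back, X)),
                   as.character(fft_predict(tree, X)))
})
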