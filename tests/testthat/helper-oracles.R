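# Independent oracles, deliberately naive, used to cross-check the
# implementation. They share no code with the package internals.

# exhaustive search over every midpoint threshold and both directions
brute_best_bacc <- function(x, labels) {
  is_low <- labels == "low"
  vs <- sort(unique(x))
  cands <- if (length(vs) > 1) (vs[-length(vs)] + vs[-1]) / 2 else vs[1]
  best <- 0.5
  for (t in cands) {
    for (dir in c("<=", ">")) {
      pred_low <- if (dir == "<=") x <= t else x > t
      hr <- sum(pred_low & is_low) / sum(is_low)
      cr <- sum(!pred_low & !is_low) / sum(!is_low)
      best <- max(best, (hr + cr) / 2)
    }
  }
  best
}

# plain trapezoid over an (x, y) point set, second implementation
trapezoid_area <- function(x, y) {
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    area <- area + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  area
}

# naive month-by-month mean for one index and one lead window
naive_window_mean <- function(indices, name, yr, months) {
  v <- vapply(months, function(m) {
    indices$value[indices$index_name == name & indices$year == yr &
                    indices$month == m]
  }, numeric(1))
  mean(v)
}

# binomial upper tail by direct pmf summation
brute_binom_tail <- function(n, k, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# random two-class labelled dataset for property sweeps
random_cue_case <- function(n, n_distinct = n) {
  x <- sample(round(rnorm(n_distinct), 2), n, replace = n_distinct < n)
  labels <- character(n)
  labels[sample(n, 1)] <- "low"
  labels[sample(which(labels == ""), 1)] <- "high"
  labels[labels == ""] <- sample(c("low", "high"), n - 2, replace = TRUE)
  list(x = x, labels = labels)
}
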