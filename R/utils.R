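# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards so no function leaks global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# classed errors so callers can distinguish expected failure modes
fc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "frugalcast_error", "error")))
}

# Deterministic 32-bit sub-seed from a base seed and a string tag. Tasks keyed
# by (region, lead) get streams that do not depend on execution order.
derive_seed <- function(seed, tag) {
  cp <- utf8ToInt(tag)
  h <- sum(cp * seq_along(cp))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629) + 1L
}

# Normalize labels to logical "is low production". Accepts character/factor
# with levels low/high, or a logical vector (TRUE = low).
as_is_low <- function(labels) {
  if (is.logical(labels)) {
    if (anyNA(labels)) fc_stop("labels contain NA", "invalid_argument")
    return(labels)
  }
  lab <- tolower(as.character(labels))
  if (anyNA(lab) || !all(lab %in% c("low", "high"))) {
    fc_stop("labels must be 'low'/'high' (or logical TRUE = low)",
            "invalid_argument")
  }
  lab == "low"
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    fc_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(miss, collapse = ", ")),
            "schema_error")
  }
  invisible(df)
}
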