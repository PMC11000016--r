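# internal helpers

# Deterministic seed splitting: every stage/substream derives its own seed
# from the master seed and a stream label, so stages are independently
# reproducible. Kept strictly below 2^31 - 1.
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 2654435.0 + 11) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# condition label from switching x trial type
conditionLabel <- function(switching, trial_type) {
  paste(switching, trial_type, sep = "-")
}

GATING_CONDITIONS <- c("switch-reference", "nonswitch-reference",
                       "switch-comparison", "nonswitch-comparison")

FREQ_BANDS <- list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30))
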