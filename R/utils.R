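# Internal validation helpers. Errors name the offending field/argument so
# callers (and config files) can be fixed without reading tracebacks.

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min) {
    abort(
      sprintf("`%s` must be a single integer >= %d (got %s).", field, min,
              paste(format(x), collapse = ", ")),
      class = "phagetrait_validation_error"
    )
  }
  as.integer(x)
}

check_fraction <- function(x, field) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1) {
    abort(
      sprintf("`%s` must be a single number in [0, 1] (got %s).", field,
              paste(format(x), collapse = ", ")),
      class = "phagetrait_validation_error"
    )
  }
  as.numeric(x)
}

check_probability_vec <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(
      sprintf("`%s` must contain probabilities in [0, 1].", field),
      class = "phagetrait_domain_error"
    )
  }
  as.numeric(x)
}

check_span <- function(x, field, max_len = Inf) {
  if (length(x) != 2L || anyNA(x) || !is.numeric(x) || any(x != floor(x)) ||
      x[1] < 1 || x[2] < x[1] || x[2] > max_len) {
    abort(
      sprintf("`%s` must be a 1-based inclusive column interval c(start, end) within the alignment (got %s).",
              field, paste(format(x), collapse = ", ")),
      class = "phagetrait_validation_error"
    )
  }
  as.integer(x)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s.", what,
              paste(missing, collapse = ", ")),
      class = "phagetrait_schema_error"
    )
  }
  invisible(df)
}

# seed derivation for multi-stage runs; stays well below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}
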