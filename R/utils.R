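# Internal validation helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Stable chronological ordering (ties keep input order).
order_stable <- function(x) order(x, seq_along(x))

new_day_index <- function(t, t0 = 0, day_length = 86400) {
  floor((t - t0) / day_length)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  list(first = ifelse(swap, b, a), second = ifelse(swap, a, b))
}
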