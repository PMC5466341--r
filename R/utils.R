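# shared input checks

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x < 0 || x > 1) abort(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# round to 1 decimal, away-from-zero halves, so means of score levels land on
# the 0.1 grid reproducibly (base round() would give half-even results)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
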