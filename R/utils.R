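# shared input checks

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    abort(sprintf("`%s` must be a non-missing numeric value.", name),
          class = "approachscan_invalid_argument")
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    abort(sprintf("`%s` must lie in %s%s, %s].", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "approachscan_invalid_argument")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name, lower = 0, strict_lower = TRUE)
}

check_nonnegative <- function(x, name) {
  check_number(x, name, lower = 0)
}
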