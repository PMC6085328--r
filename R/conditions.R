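# Classed conditions so callers can distinguish bad arguments, bad
# configuration, numerical failure and fit failure programmatically.

cco_abort <- function(message, class, ...) {
  stop(errorCondition(message, ...,
                      class = c(class, "ccoflash_error", "error")))
}

abort_invalid <- function(message, ...) {
  cco_abort(message, "ccoflash_invalid_argument", ...)
}

abort_config <- function(message, ...) {
  cco_abort(message, "ccoflash_config_error", ...)
}

abort_numerical <- function(message, ...) {
  cco_abort(message, "ccoflash_numerical_failure", ...)
}

abort_fit <- function(message, ...) {
  cco_abort(message, "ccoflash_fit_failure", ...)
}

abort_ambiguous <- function(message, ...) {
  cco_abort(message, "ccoflash_ambiguous_component", ...)
}

abort_degenerate <- function(message, ...) {
  cco_abort(message, "ccoflash_degenerate_fit", ...)
}

# scalar validation helper; `lower`/`upper` are open bounds when strict
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    abort_invalid(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}
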