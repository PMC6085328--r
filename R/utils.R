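# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Logarithmic time grid
#'
#' Convenience constructor for the log-spaced sampling grid used by the
#' flash-trace simulator: `n` points equally spaced in log time between
#' `t_min` and `t_max` (seconds).  Time zero is the photolysis flash, so
#' the grid starts strictly after it.
#'
#' @param t_min,t_max grid limits in seconds (both > 0).
#' @param n number of points.
#' @return Strictly increasing numeric vector of times in seconds.
#' @examples
#' tg <- log_time_grid(1e-6, 0.1, 50)
#' range(tg)
#' @export
log_time_grid <- function(t_min = 1e-6, t_max = 0.1, n = 400L) {
  check_number(t_min, "t_min", lower = 0, strict_lower = TRUE)
  check_number(t_max, "t_max", lower = t_min, strict_lower = TRUE)
  check_number(n, "n", lower = 2)
  exp(seq(log(t_min), log(t_max), length.out = as.integer(n)))
}
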