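#' Nernst equilibrium potential for an ion gradient
#'
#' `E = (R * T / (z * F)) * ln(c_out / c_in)` in mV.  Used to convert
#' valinomycin-mediated K+ gradients into the membrane potentials that
#' calibrate the oxonol dye response.
#'
#' @param c_out,c_in external and internal ion concentrations (any
#'   common unit, both > 0).
#' @param charge ion charge number z (non-zero integer; +1 for K+).
#' @param temperature absolute temperature in K.
#' @return Potential in mV.
#' @examples
#' nernst_potential(50, 0.5)  # ~118.3 mV, the top of the K+ series
#' @export
nernst_potential <- function(c_out, c_in, charge = 1L, temperature = 298.15) {
  check_number(c_out, "c_out", lower = 0, strict_lower = TRUE)
  check_number(c_in, "c_in", lower = 0, strict_lower = TRUE)
  check_number(charge, "charge")
  if (charge == 0) abort_invalid("`charge` must be non-zero")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  (.R_GAS * temperature / (charge * .FARADAY)) * log(c_out / c_in) * 1000
}

#' Dye-calibration series
#'
#' One row per imposed K+ gradient: external concentration, internal
#' concentration, and the observed dye absorbance change.
#'
#' @param k_out_mM,k_in_mM external/internal K+ concentrations in mM.
#' @param delta_a observed dye absorbance change per gradient.
#' @return An object of class `calibration_series` (a data frame).
#' @export
calibration_series <- function(k_out_mM, k_in_mM, delta_a) {
  if (any(!is.finite(k_out_mM)) || any(k_out_mM <= 0) ||
      any(!is.finite(k_in_mM)) || any(k_in_mM <= 0)) {
    abort_invalid("concentrations must be finite and > 0")
  }
  if (length(delta_a) != length(k_out_mM) ||
      !(length(k_in_mM) %in% c(1L, length(k_out_mM)))) {
    abort_invalid("column lengths are inconsistent")
  }
  out <- data.frame(k_out_mM = k_out_mM,
                    k_in_mM = rep_len(k_in_mM, length(k_out_mM)),
                    delta_a = delta_a)
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Fit a linear dye-response calibration curve
#'
#' Converts each gradient to a Nernst potential and fits the ordinary
#' least-squares line `dA = intercept + slope * E`.  The dye response is
#' modeled as linear in potential over the calibrated range (0 to
#' ~120 mV for the standard K+ series); possible saturation at high
#' potential is not modeled.
#'
#' @param series a [calibration_series()] with >= 2 points at distinct
#'   potentials.
#' @param charge ion charge number (default +1, K+).
#' @param temperature absolute temperature in K.
#' @return An object of class `calibration_curve`: list with `slope`
#'   (dA per mV), `intercept` (dA), `sigma` (residual SD) and the
#'   per-point potentials.
#' @examples
#' s <- calibration_series(c(2.5, 5, 10, 20, 40, 50), 0.5,
#'                         1e-3 * nernst_potential(c(2.5, 5, 10, 20, 40, 50), 0.5))
#' fit_calibration(s)$slope  # 1e-3
#' @export
fit_calibration <- function(series, charge = 1L, temperature = 298.15) {
  if (!is.data.frame(series) ||
      !all(c("k_out_mM", "k_in_mM", "delta_a") %in% names(series))) {
    abort_invalid("`series` must have columns k_out_mM, k_in_mM, delta_a")
  }
  if (nrow(series) < 2L) {
    abort_degenerate("calibration needs at least two points")
  }
  potential <- mapply(nernst_potential, series$k_out_mM, series$k_in_mM,
                      MoreArgs = list(charge = charge,
                                      temperature = temperature))
  if (diff(range(potential)) < 1e-9) {
    abort_degenerate("all calibration points are at the same potential")
  }
  fit <- lm(delta_a ~ potential, data = data.frame(
    delta_a = series$delta_a, potential = potential))
  res <- stats::residuals(fit)
  dof <- length(res) - 2L
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         sigma = if (dof > 0) sqrt(sum(res^2) / dof) else 0,
         potentials_mV = potential,
         charge = charge,
         temperature_K = temperature),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> slope %.4g dA/mV, intercept %.4g, sigma %.3g (%d pts, %0.1f-%0.1f mV)\n",
    x$slope, x$intercept, x$sigma, length(x$potentials_mV),
    min(x$potentials_mV), max(x$potentials_mV)))
  cat("note: linearity outside the calibrated range is an assumption\n")
  invisible(x)
}

#' Estimate a membrane potential from a dye response
#'
#' Inverts the linear calibration: `E = (dA - intercept) / slope`.
#'
#' @param delta_a observed dye absorbance change (vectorized).
#' @param curve a [fit_calibration()] result.
#' @return Estimated potential(s) in mV.
#' @export
estimate_potential <- function(delta_a, curve) {
  if (!inherits(curve, "calibration_curve")) {
    abort_invalid("`curve` must be a calibration_curve")
  }
  if (!is.numeric(delta_a) || any(!is.finite(delta_a))) {
    abort_invalid("`delta_a` must be finite")
  }
  if (!is.finite(curve$slope) || curve$slope == 0) {
    abort_invalid("calibration curve has zero slope; unusable")
  }
  (delta_a - curve$intercept) / curve$slope
}

#' Respiratory control ratio
#'
#' Ratio of the uncoupled (e.g., + FCCP) to the coupled O2-reduction
#' rate; values above 1 indicate an intact, coupled membrane.
#'
#' @param rate_coupled,rate_uncoupled O2-consumption rates in uM O2/s
#'   (both > 0).
#' @return The dimensionless ratio `rate_uncoupled / rate_coupled`.
#' @examples
#' rcr(0.10, 0.13)  # 1.3
#' @export
rcr <- function(rate_coupled, rate_uncoupled) {
  check_number(rate_coupled, "rate_coupled", lower = 0, strict_lower = TRUE)
  check_number(rate_uncoupled, "rate_uncoupled", lower = 0,
               strict_lower = TRUE)
  rate_uncoupled / rate_coupled
}

#' Oxygen-electrode time course
#'
#' @param times times in seconds, strictly increasing.
#' @param o2_uM dissolved O2 concentrations in uM.
#' @param additions data frame with columns `label`, `time_s`
#'   annotating additions (sample, uncoupler, ...).
#' @return An object of class `oxygen_trace` (data frame `time_s`,
#'   `o2_uM` with an `additions` attribute).
#' @export
oxygen_trace <- function(times, o2_uM,
                         additions = data.frame(label = character(),
                                                time_s = numeric())) {
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort_invalid("`times` must be finite and strictly increasing")
  }
  if (length(o2_uM) != length(times)) {
    abort_invalid("`o2_uM` and `times` lengths differ")
  }
  out <- data.frame(time_s = times, o2_uM = o2_uM)
  attr(out, "additions") <- additions
  class(out) <- c("oxygen_trace", "data.frame")
  out
}

#' Extract an O2-consumption rate from an electrode trace
#'
#' Least-squares slope magnitude of `[O2]` against time within a
#' window, in uM O2/s.
#'
#' @param trace an [oxygen_trace()].
#' @param window length-2 time interval in seconds, within the trace
#'   span, containing >= 3 points.
#' @return Rate magnitude in uM O2/s.
#' @export
extract_o2_rate <- function(trace, window) {
  if (!is.data.frame(trace) || !all(c("time_s", "o2_uM") %in% names(trace))) {
    abort_invalid("`trace` must have columns time_s and o2_uM")
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    abort_invalid("`window` must be an increasing time interval")
  }
  if (window[1] < min(trace$time_s) || window[2] > max(trace$time_s)) {
    abort_invalid("`window` must lie within the trace span")
  }
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2] &
    is.finite(trace$o2_uM)
  if (sum(sel) < 3L) {
    abort_invalid("window contains fewer than 3 points")
  }
  fit <- lm(o2_uM ~ time_s, data = trace[sel, ])
  abs(unname(coef(fit)[2]))
}
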