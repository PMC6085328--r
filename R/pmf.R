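#' Proton-motive force from its electrical and pH components
#'
#' Combines a transmembrane electrical potential and a pH gradient into
#' the proton-motive force, `Dp = dPsi + Z * dpH`, where
#' `Z = ln(10) * R * T / F` (about 59.16 mV at 298.15 K).
#'
#' @param delta_psi electrical potential difference in mV (positive =
#'   opposing outward proton pumping by CytcO).
#' @param delta_ph pH gradient in pH units contributing to the force.
#' @param temperature absolute temperature in K.
#' @return Proton-motive force in mV.
#' @examples
#' pmf(100, 0.4)  # ~123.7 mV, the conditions generated by ATP hydrolysis
#' @seealso [pmf_state()], [scale_rate_for_pmf()]
#' @export
pmf <- function(delta_psi, delta_ph, temperature = 298.15) {
  check_number(delta_psi, "delta_psi")
  check_number(delta_ph, "delta_ph")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  delta_psi + nernst_slope_mv(temperature) * delta_ph
}

#' Nernst slope ln(10)RT/F in mV
#'
#' The per-pH-unit (or per-decade) potential equivalent used by [pmf()]
#' and [nernst_potential()]; about 59.16 mV at 298.15 K.
#'
#' @param temperature absolute temperature in K.
#' @return Slope in mV per decade.
#' @export
nernst_slope_mv <- function(temperature = 298.15) {
  log(10) * .R_GAS * temperature / .FARADAY * 1000
}

#' Membrane energization state
#'
#' Bundles the electrical potential, the pH gradient and the temperature,
#' together with the derived proton-motive force, into a single object
#' consumed by [build_rate_matrix()] and the synthetic-data generators.
#'
#' @inheritParams pmf
#' @return An object of class `pmf_state` with fields `delta_psi_mV`,
#'   `delta_ph`, `temperature_K` and the derived `pmf_mV`.
#' @examples
#' pmf_state(100, 0.4)   # ATP-energized sub-mitochondrial particles
#' pmf_state(0, 0)       # uncoupled (valinomycin + FCCP) condition
#' @export
pmf_state <- function(delta_psi = 0, delta_ph = 0, temperature = 298.15) {
  structure(
    list(delta_psi_mV = delta_psi,
         delta_ph = delta_ph,
         temperature_K = temperature,
         pmf_mV = pmf(delta_psi, delta_ph, temperature)),
    class = "pmf_state")
}

#' @export
print.pmf_state <- function(x, ...) {
  cat(sprintf(
    "<pmf_state> dPsi = %g mV, dpH = %g, T = %g K  =>  Dp = %.2f mV\n",
    x$delta_psi_mV, x$delta_ph, x$temperature_K, x$pmf_mV))
  invisible(x)
}

#' Boltzmann scaling of an electrogenic rate by the proton-motive force
#'
#' Charge translocation against a proton-motive force loses driving
#' force; the rate of an electrogenic step is scaled as
#' `k = k0 * exp(-q * F * Dp / (R * T))`, with a single effective charge
#' `q` per transition (any transfer coefficient and dielectric distance
#' are absorbed into `q`).  With `q = 0` or zero force, the rate is
#' unchanged.
#'
#' @param k0 base rate constant in s^-1 (> 0).
#' @param q effective electrogenic charge, dimensionless, >= 0.
#' @param pmf_mv proton-motive force in mV (see [pmf()]).
#' @param temperature absolute temperature in K.
#' @return Scaled rate constant in s^-1.
#' @examples
#' scale_rate_for_pmf(2000, q = 1, pmf_mv = pmf(100, 0.4))  # ~16 s^-1
#' scale_rate_for_pmf(2000, q = 0, pmf_mv = 200)            # unchanged
#' @export
scale_rate_for_pmf <- function(k0, q, pmf_mv, temperature = 298.15) {
  check_number(k0, "k0", lower = 0, strict_lower = TRUE)
  check_number(q, "q", lower = 0)
  check_number(pmf_mv, "pmf_mv")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  k0 * exp(-q * .FARADAY * (pmf_mv / 1000) / (.R_GAS * temperature))
}

#' Pseudo-first-order rate of O2 binding
#'
#' The bimolecular O2-binding step R -> A becomes first order at fixed
#' dissolved O2: `k = k2 * [O2]`, so its time constant is
#' `tau = 1 / (k2 * [O2])` (about 10 us at 1 mM O2 for CytcO).
#'
#' @param k2 second-order rate constant in M^-1 s^-1 (> 0).
#' @param o2_conc dissolved O2 concentration in M (> 0).
#' @return First-order rate constant in s^-1.
#' @examples
#' 1 / pseudo_first_order_rate(1e8, 1e-3)    # 10 us
#' 1 / pseudo_first_order_rate(1e8, 0.5e-3)  # 20 us after 1:1 mixing
#' @export
pseudo_first_order_rate <- function(k2, o2_conc) {
  check_number(k2, "k2", lower = 0, strict_lower = TRUE)
  check_number(o2_conc, "o2_conc", lower = 0, strict_lower = TRUE)
  k2 * o2_conc
}
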