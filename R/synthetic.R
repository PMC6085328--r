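#' Configuration for a synthetic flow-flash experiment
#'
#' Collects every knob of the simulated instrument.  Defaults emulate
#' the standard sub-mitochondrial-particle experiment: 0.5 mM O2 after
#' 1:1 mixing of an O2-saturated (~1.2 mM) buffer, a 1.00-cm cuvette,
#' two detection wavelengths (445 and 605 nm), a logarithmic time grid
#' from 1 us to 100 ms with t = 0 at the photolysis flash, additive
#' Gaussian noise of 0.002 dA, and a blanked laser-artifact window over
#' the first 2 us.
#'
#' @param scheme a [reaction_scheme()]; default [default_cco_scheme()].
#' @param pmf_state a [pmf_state()]; default de-energized.
#' @param epsilon an [epsilon_table()]; default
#'   [default_epsilon_table()].
#' @param o2_conc dissolved O2 in M.
#' @param enzyme_conc enzyme concentration in mM.
#' @param path cuvette path length in cm.
#' @param wavelengths wavelengths to record, nm.
#' @param times sampling grid in s (strictly increasing, > 0).
#' @param noise_sd additive Gaussian noise SD in dA units (>= 0).
#' @param blank_window length-2 flash-artifact window in s whose points
#'   are replaced by NA.
#' @param seed integer RNG seed.
#' @return A list of class `flash_trace_config`.
#' @export
flash_trace_config <- function(scheme = default_cco_scheme(),
                               pmf_state = ccoflash::pmf_state(0, 0),
                               epsilon = default_epsilon_table(),
                               o2_conc = 0.5e-3,
                               enzyme_conc = 1e-3,
                               path = 1,
                               wavelengths = c(445, 605),
                               times = log_time_grid(1e-6, 0.1, 400L),
                               noise_sd = 0.002,
                               blank_window = c(0, 2e-6),
                               seed = 1L) {
  if (!inherits(scheme, "reaction_scheme")) {
    abort_config("`scheme` must be a reaction_scheme")
  }
  if (!inherits(pmf_state, "pmf_state")) {
    abort_config("`pmf_state` must be a pmf_state")
  }
  if (!inherits(epsilon, "epsilon_table")) {
    abort_config("`epsilon` must be an epsilon_table")
  }
  check_number(o2_conc, "o2_conc", lower = 0, strict_lower = TRUE)
  check_number(enzyme_conc, "enzyme_conc", lower = 0, strict_lower = TRUE)
  check_number(path, "path", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(blank_window) != 2L || blank_window[1] > blank_window[2]) {
    abort_config("`blank_window` must be an interval")
  }
  structure(
    list(scheme = scheme, pmf_state = pmf_state, epsilon = epsilon,
         o2_conc = o2_conc, enzyme_conc = enzyme_conc, path = path,
         wavelengths = wavelengths, times = times, noise_sd = noise_sd,
         blank_window = blank_window, seed = as.integer(seed)),
    class = "flash_trace_config")
}

#' Simulate a flash-photolysis trace pair
#'
#' Solves the catalytic-cycle populations for the configured scheme and
#' energization, projects them through the epsilon table at each
#' configured wavelength, adds i.i.d. Gaussian noise, and blanks the
#' laser-artifact window with NA.  A pure function of (config, seed):
#' identical configurations give bit-identical traces.  The noise-free
#' model and all generating parameters are carried in a `ground_truth`
#' attribute so recovery tests are self-contained.
#'
#' @param config a [flash_trace_config()].
#' @return Named list of [cco_trace()] objects, one per wavelength
#'   (names like `"445"`), with attribute `ground_truth` (list holding
#'   the trajectory, noise-free traces and parameters).
#' @examples
#' cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 100), seed = 7)
#' traces <- generate_flash_traces(cfg)
#' names(traces)
#' @export
generate_flash_traces <- function(config) {
  if (!inherits(config, "flash_trace_config")) {
    abort_config("`config` must be a flash_trace_config")
  }
  K <- build_rate_matrix(config$scheme, config$o2_conc, config$pmf_state)
  traj <- solve_populations(K, times = config$times)
  clean <- lapply(config$wavelengths, function(wl) {
    populations_to_absorbance(traj, config$epsilon, wl,
                              enzyme_conc = config$enzyme_conc,
                              path = config$path)
  })
  names(clean) <- as.character(config$wavelengths)
  blank <- config$times >= config$blank_window[1] &
    config$times <= config$blank_window[2]
  noisy <- with_seed(config$seed, lapply(clean, function(tr) {
    da <- tr$delta_a + rnorm(nrow(tr), sd = config$noise_sd)
    da[blank] <- NA_real_
    cco_trace(attr(tr, "wavelength_nm"), tr$time_s, da,
              path_cm = config$path,
              meta = list(o2_conc_M = config$o2_conc,
                          delta_psi_mV = config$pmf_state$delta_psi_mV,
                          delta_ph = config$pmf_state$delta_ph,
                          temperature_K = config$pmf_state$temperature_K,
                          enzyme_conc_mM = config$enzyme_conc,
                          noise_sd = config$noise_sd,
                          seed = config$seed))
  }))
  attr(noisy, "ground_truth") <- list(trajectory = traj,
                                      noise_free = clean,
                                      config = config)
  noisy
}

#' Simulate replicated traces under paired energization conditions
#'
#' Generates `replicates` independent noisy trace pairs for each of two
#' membrane states (e.g., uncoupled versus ATP-energized).  Kinetics are
#' identical within a condition; noise is independent per replicate and
#' per condition, with per-replicate seeds derived deterministically
#' from `seed`.
#'
#' @param config a [flash_trace_config()]; its own `pmf_state` and
#'   `seed` are overridden per condition/replicate.
#' @param pmf_off,pmf_on [pmf_state()] objects for the two conditions;
#'   defaults are a de-energized membrane and the ATP-energized state
#'   (100 mV, 0.4 pH units).
#' @param replicates number of replicates per condition (>= 1).
#' @param seed master seed.
#' @return List with elements `off` and `on`, each a list of
#'   `replicates` trace sets as from [generate_flash_traces()].
#' @export
generate_paired_condition_traces <- function(config = flash_trace_config(),
                                             pmf_off = pmf_state(0, 0),
                                             pmf_on = pmf_state(100, 0.4),
                                             replicates = 1L,
                                             seed = 1L) {
  check_number(replicates, "replicates", lower = 1)
  replicates <- as.integer(replicates)
  seeds <- derive_seeds(seed, 2L * replicates)
  one_condition <- function(pmfst, seed_offset) {
    lapply(seq_len(replicates), function(i) {
      cfg <- config
      cfg$pmf_state <- pmfst
      cfg$seed <- seeds[seed_offset + i]
      generate_flash_traces(cfg)
    })
  }
  list(off = one_condition(pmf_off, 0L),
       on = one_condition(pmf_on, replicates))
}

#' Simulate a dye-calibration series
#'
#' Generates `dA = slope * E_Nernst + intercept + noise` over a K+
#' concentration series (defaults: the standard 2.5-50 mM external
#' series against 0.5 mM internal).
#'
#' @param slope true dye response in dA per mV.
#' @param intercept true dA offset.
#' @param k_out_mM external K+ concentrations in mM.
#' @param k_in_mM internal K+ concentration in mM.
#' @param noise_sd Gaussian dA noise SD.
#' @param seed integer seed.
#' @param charge ion charge (default +1).
#' @param temperature absolute temperature in K.
#' @return A [calibration_series()] with attribute `ground_truth`.
#' @export
generate_calibration_series <- function(slope = 1e-3, intercept = 0,
                                        k_out_mM = c(2.5, 5, 10, 20, 40, 50),
                                        k_in_mM = 0.5,
                                        noise_sd = 5e-4, seed = 1L,
                                        charge = 1L, temperature = 298.15) {
  if (any(!is.finite(k_out_mM)) || any(k_out_mM <= 0)) {
    abort_invalid("`k_out_mM` must be finite and > 0")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  potentials <- vapply(k_out_mM, nernst_potential, numeric(1),
                       c_in = k_in_mM, charge = charge,
                       temperature = temperature)
  da <- slope * potentials + intercept +
    with_seed(seed, rnorm(length(k_out_mM), sd = noise_sd))
  out <- calibration_series(k_out_mM, k_in_mM, da)
  attr(out, "ground_truth") <- list(slope = slope, intercept = intercept,
                                    potentials_mV = potentials,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a coupled/uncoupled oxygen-electrode trace
#'
#' Piecewise-linear O2 decline: the coupled rate before `switch_time`
#' (uncoupler addition) and the uncoupled rate after, plus Gaussian
#' noise.  The switch is annotated in the trace.
#'
#' @param rate_coupled,rate_uncoupled O2-consumption rates in uM O2/s
#'   (>= 0).
#' @param switch_time uncoupler-addition time in s.
#' @param noise_sd Gaussian noise SD in uM.
#' @param seed integer seed.
#' @param o2_start initial O2 concentration in uM.
#' @param duration trace length in s.
#' @param dt sampling interval in s.
#' @return An [oxygen_trace()] with attribute `ground_truth`.
#' @export
generate_oxygen_trace <- function(rate_coupled = 0.10,
                                  rate_uncoupled = 0.13,
                                  switch_time = 300, noise_sd = 0.5,
                                  seed = 1L, o2_start = 240,
                                  duration = 600, dt = 1) {
  check_number(rate_coupled, "rate_coupled", lower = 0)
  check_number(rate_uncoupled, "rate_uncoupled", lower = 0)
  check_number(switch_time, "switch_time", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  times <- seq(0, duration, by = dt)
  o2 <- ifelse(times <= switch_time,
               o2_start - rate_coupled * times,
               o2_start - rate_coupled * switch_time -
                 rate_uncoupled * (times - switch_time))
  o2 <- o2 + with_seed(seed, rnorm(length(times), sd = noise_sd))
  out <- oxygen_trace(times, o2,
                      additions = data.frame(label = "uncoupler",
                                             time_s = switch_time))
  attr(out, "ground_truth") <- list(rate_coupled = rate_coupled,
                                    rate_uncoupled = rate_uncoupled,
                                    switch_time = switch_time,
                                    noise_sd = noise_sd, seed = seed)
  out
}
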