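# Shared CSV dialect: optional '# key = value' metadata lines, then a
# header row and comma-separated data.

write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v)) next
    writeLines(sprintf("# %s = %s", k,
                       paste(format(v, digits = 15), collapse = " ")), con)
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (line in lines[is_meta]) {
    body <- sub("^#\\s*", "", line)
    kv <- strsplit(body, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  df <- read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  list(data = df, meta = meta)
}

#' Write / read an absorbance trace
#'
#' Traces are stored as CSV with columns `time_s`, `delta_a`, preceded
#' by `#`-prefixed metadata lines (wavelength, path, O2 concentration,
#' energization, noise SD, seed, ...).
#'
#' @param trace a [cco_trace()].
#' @param path file path.
#' @return `write_trace()` returns the path invisibly; `read_trace()`
#'   returns a [cco_trace()].
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "cco_trace")) abort_invalid("`trace` must be a cco_trace")
  meta <- c(list(wavelength_nm = attr(trace, "wavelength_nm"),
                 path_cm = attr(trace, "path_cm")),
            attr(trace, "meta"))
  write_csv_meta(as.data.frame(trace), path, meta)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  parsed <- read_csv_meta(path)
  df <- parsed$data
  if (!all(c("time_s", "delta_a") %in% names(df))) {
    abort_config(sprintf("%s is not a trace file (need time_s, delta_a)", path))
  }
  meta <- parsed$meta
  wl <- meta$wavelength_nm %||% NA_real_
  pl <- meta$path_cm %||% 1
  meta$wavelength_nm <- NULL
  meta$path_cm <- NULL
  cco_trace(wl, df$time_s, df$delta_a, path_cm = pl, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a population trajectory
#'
#' CSV with column `time_s` followed by one occupancy column per state,
#' plus `#` metadata lines (O2 concentration, energization).
#'
#' @param traj a [population_trajectory()].
#' @param path file path.
#' @param meta optional named list of metadata values.
#' @return `write_trajectory()` returns the path invisibly;
#'   `read_trajectory()` returns a [population_trajectory()].
#' @export
write_trajectory <- function(traj, path, meta = list()) {
  if (!inherits(traj, "population_trajectory")) {
    abort_invalid("`traj` must be a population_trajectory")
  }
  write_csv_meta(as.data.frame(traj), path, meta)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  parsed <- read_csv_meta(path)
  df <- parsed$data
  if (names(df)[1] != "time_s" || ncol(df) < 3L) {
    abort_config(sprintf("%s is not a trajectory file", path))
  }
  population_trajectory(df$time_s, as.matrix(df[-1]))
}

#' Write / read an epsilon table
#'
#' Delimited text with columns `state`, `wavelength_nm`, `epsilon` and
#' `#` metadata lines.
#'
#' @param eps an [epsilon_table()].
#' @param path file path.
#' @return `write_epsilon_table()` returns the path invisibly;
#'   `read_epsilon_table()` returns an [epsilon_table()].
#' @export
write_epsilon_table <- function(eps, path) {
  if (!inherits(eps, "epsilon_table")) {
    abort_invalid("`eps` must be an epsilon_table")
  }
  write_csv_meta(as.data.frame(eps), path,
                 list(reference_state = "O",
                      units_445 = "mM^-1 cm^-1",
                      units_605 = "relative (total = 100)"))
}

#' @rdname write_epsilon_table
#' @export
read_epsilon_table <- function(path) {
  parsed <- read_csv_meta(path)
  epsilon_table(parsed$data)
}

#' Write / read a dye-calibration series
#'
#' @param series a [calibration_series()].
#' @param path file path.
#' @return `write_calibration_series()` returns the path invisibly;
#'   `read_calibration_series()` returns a [calibration_series()].
#' @export
write_calibration_series <- function(series, path) {
  if (!inherits(series, "calibration_series")) {
    abort_invalid("`series` must be a calibration_series")
  }
  write_csv_meta(as.data.frame(series), path, list())
}

#' @rdname write_calibration_series
#' @export
read_calibration_series <- function(path) {
  parsed <- read_csv_meta(path)
  df <- parsed$data
  if (!all(c("k_out_mM", "k_in_mM", "delta_a") %in% names(df))) {
    abort_config(sprintf("%s is not a calibration-series file", path))
  }
  calibration_series(df$k_out_mM, df$k_in_mM, df$delta_a)
}

#' Write / read an oxygen-electrode trace
#'
#' CSV with columns `time_s`, `o2_uM`; additions are stored as
#' `# addition_<label> = <time>` metadata lines.
#'
#' @param trace an [oxygen_trace()].
#' @param path file path.
#' @return `write_oxygen_trace()` returns the path invisibly;
#'   `read_oxygen_trace()` returns an [oxygen_trace()].
#' @export
write_oxygen_trace <- function(trace, path) {
  if (!inherits(trace, "oxygen_trace")) {
    abort_invalid("`trace` must be an oxygen_trace")
  }
  adds <- attr(trace, "additions")
  meta <- list()
  if (!is.null(adds) && nrow(adds)) {
    meta <- setNames(as.list(adds$time_s), paste0("addition_", adds$label))
  }
  write_csv_meta(as.data.frame(trace), path, meta)
}

#' @rdname write_oxygen_trace
#' @export
read_oxygen_trace <- function(path) {
  parsed <- read_csv_meta(path)
  df <- parsed$data
  if (!all(c("time_s", "o2_uM") %in% names(df))) {
    abort_config(sprintf("%s is not an oxygen-trace file", path))
  }
  keys <- names(parsed$meta)
  addkeys <- keys[startsWith(keys, "addition_")]
  adds <- data.frame(label = sub("^addition_", "", addkeys),
                     time_s = as.numeric(unlist(parsed$meta[addkeys],
                                                use.names = FALSE)))
  oxygen_trace(df$time_s, df$o2_uM, additions = adds)
}

#' Write / read a fit result as JSON
#'
#' Serializes components (amplitude, tau), offset, residual statistics
#' and convergence flag; the raw fitted points are not stored.
#'
#' @param fit a [fit_multiexponential()] result.
#' @param path file path.
#' @return `write_fit_result()` returns the path invisibly;
#'   `read_fit_result()` returns a list with the stored fields.
#' @export
write_fit_result <- function(fit, path) {
  if (!inherits(fit, "fit_result")) abort_invalid("`fit` must be a fit_result")
  out <- list(components = fit$components,
              offset = fit$offset,
              rss = fit$rss,
              sigma = fit$sigma,
              n_points = fit$n_points,
              n_components = fit$n_components,
              converged = fit$converged,
              tau_bounds = fit$tau_bounds,
              seed = fit$seed,
              wavelength_nm = fit$wavelength_nm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# -- JSON run configuration ------------------------------------------------

scheme_config_keys <- c(
  "o2_conc_M", "enzyme_conc_mM", "path_cm", "wavelengths_nm",
  "t_min_s", "t_max_s", "n_points", "noise_sd", "blank_window_s",
  "delta_psi_mV", "delta_ph", "temperature_K",
  "f_a", "eps_site_F_R_445", "eps_site_F_R_605",
  "k_r_a_M_s", "k_a_pr_s", "k_pr_f_s", "k_f_fr_s", "k_fr_o_s",
  "q_r_a", "q_a_pr", "q_pr_f", "q_f_fr", "q_fr_o", "seed")

#' Read a flash-simulation configuration from a JSON file
#'
#' Flat key-value JSON; unknown keys are rejected.  Recognized keys
#' cover the scheme base rates and charges (`k_*`, `q_*`), the
#' energization (`delta_psi_mV`, `delta_ph`, `temperature_K`), the
#' epsilon-table parameters (`f_a`, `eps_site_F_R_445`,
#' `eps_site_F_R_605`), the instrument (`o2_conc_M`, `enzyme_conc_mM`,
#' `path_cm`, `wavelengths_nm`, `t_min_s`, `t_max_s`, `n_points`,
#' `noise_sd`, `blank_window_s`) and `seed`.  Missing keys fall back to
#' the package defaults.
#'
#' @param path JSON file path.
#' @return A [flash_trace_config()].
#' @export
read_flash_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_config(
                    sprintf("cannot parse config %s: %s", path,
                            conditionMessage(e))))
  unknown <- setdiff(names(raw), scheme_config_keys)
  if (length(unknown)) {
    abort_config(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  g <- function(key, default) raw[[key]] %||% default
  scheme <- default_cco_scheme(
    k_r_a = g("k_r_a_M_s", 1e8),
    k_a_pr = g("k_a_pr_s", 1 / 30e-6),
    k_pr_f = g("k_pr_f_s", 1e4),
    k_f_fr = g("k_f_fr_s", 200),
    k_fr_o = g("k_fr_o_s", 2000),
    q_r_a = g("q_r_a", 0), q_a_pr = g("q_a_pr", 0),
    q_pr_f = g("q_pr_f", 0), q_f_fr = g("q_f_fr", 0),
    q_fr_o = g("q_fr_o", 1))
  flash_trace_config(
    scheme = scheme,
    pmf_state = pmf_state(g("delta_psi_mV", 0), g("delta_ph", 0),
                          g("temperature_K", 298.15)),
    epsilon = default_epsilon_table(
      f_a = g("f_a", 1),
      eps_site_f_r_445 = g("eps_site_F_R_445", 10),
      eps_site_f_r_605 = g("eps_site_F_R_605", 4)),
    o2_conc = g("o2_conc_M", 0.5e-3),
    enzyme_conc = g("enzyme_conc_mM", 1e-3),
    path = g("path_cm", 1),
    wavelengths = g("wavelengths_nm", c(445, 605)),
    times = log_time_grid(g("t_min_s", 1e-6), g("t_max_s", 0.1),
                          g("n_points", 400L)),
    noise_sd = g("noise_sd", 0.002),
    blank_window = g("blank_window_s", c(0, 2e-6)),
    seed = g("seed", 1L))
}
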