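test_that("zero-noise generation equals the deterministic projection", {
  cfg <- flash_trace_config(noise_sd = 0,
                            times = log_time_grid(1e-6, 0.1, 100),
                            blank_window = c(0, 0))
  traces <- generate_flash_traces(cfg)
  gt <- attr(traces, "ground_truth")
  expect_equal(traces[["445"]]$delta_a, gt$noise_free[["445"]]$delta_a)
  expect_equal(traces[["605"]]$delta_a, gt$noise_free[["605"]]$delta_a)
})

test_that("generation is bit-identical for equal seeds, different otherwise", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 100), seed = 3)
  a <- generate_flash_traces(cfg)
  b <- generate_flash_traces(cfg)
  expect_identical(a[["445"]]$delta_a, b[["445"]]$delta_a)
  cfg2 <- cfg; cfg2$seed <- 4L
  c_ <- generate_flash_traces(cfg2)
  expect_false(identical(a[["445"]]$delta_a, c_[["445"]]$delta_a))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_flash_traces(
    flash_trace_config(times = log_time_grid(1e-6, 0.1, 50))))
  expect_identical(.Random.seed, before)
})

test_that("injected noise has the configured scale", {
  cfg <- flash_trace_config(noise_sd = 0.002,
                            times = log_time_grid(1e-6, 0.1, 400),
                            blank_window = c(0, 0), seed = 10)
  traces <- generate_flash_traces(cfg)
  gt <- attr(traces, "ground_truth")
  resid <- traces[["445"]]$delta_a - gt$noise_free[["445"]]$delta_a
  expect_lt(abs(sd(resid) - 0.002) / 0.002, 0.15)
  expect_lt(abs(mean(resid)), 3 * 0.002 / sqrt(length(resid)))
})

test_that("flash-artifact window is blanked with NA", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 100),
                            blank_window = c(0, 2e-6))
  tr <- generate_flash_traces(cfg)[["445"]]
  in_win <- tr$time_s <= 2e-6
  expect_true(all(is.na(tr$delta_a[in_win])))
  expect_true(all(is.finite(tr$delta_a[!in_win])))
})

test_that("paired conditions differ only where the pmf acts", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 150),
                            noise_sd = 0)
  paired <- generate_paired_condition_traces(cfg, replicates = 1, seed = 5)
  off <- paired$off[[1]][["445"]]
  on <- paired$on[[1]][["445"]]
  # sub-ms kinetics are unchanged: traces agree early
  early <- off$time_s < 2e-4 & is.finite(off$delta_a)
  expect_lt(max(abs(off$delta_a[early] - on$delta_a[early])), 2e-4)
  # the energized trace decays less by 100 ms (blocked proton uptake)
  expect_gt(on$delta_a[150], off$delta_a[150])
})

test_that("null condition pair shows no effect (negative control)", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 150),
                            noise_sd = 0)
  paired <- generate_paired_condition_traces(cfg, pmf_on = pmf_state(0, 0),
                                             replicates = 1, seed = 5)
  expect_equal(paired$off[[1]][["445"]]$delta_a,
               paired$on[[1]][["445"]]$delta_a, tolerance = 1e-12)
})

test_that("replicates are independent but share kinetics", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 100))
  paired <- generate_paired_condition_traces(cfg, replicates = 3, seed = 9)
  expect_length(paired$off, 3)
  expect_length(paired$on, 3)
  expect_false(identical(paired$off[[1]][["445"]]$delta_a,
                         paired$off[[2]][["445"]]$delta_a))
  gt1 <- attr(paired$off[[1]], "ground_truth")
  gt2 <- attr(paired$off[[2]], "ground_truth")
  expect_identical(gt1$noise_free[["445"]]$delta_a,
                   gt2$noise_free[["445"]]$delta_a)
})

test_that("end-to-end: paired_amplitude_decrease is positive at 445 nm", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 300))
  paired <- generate_paired_condition_traces(cfg, replicates = 1, seed = 2)
  res <- paired_amplitude_decrease(paired, seed = 2)
  expect_equal(nrow(res), 1L)
  expect_gt(res$percent_decrease, 5)
  expect_lt(res$percent_decrease, 30)
})

test_that("config validation", {
  expect_error(flash_trace_config(noise_sd = -1),
               class = "ccoflash_invalid_argument")
  expect_error(flash_trace_config(o2_conc = 0),
               class = "ccoflash_invalid_argument")
  expect_error(flash_trace_config(scheme = "x"),
               class = "ccoflash_config_error")
  expect_error(generate_flash_traces(list()),
               class = "ccoflash_config_error")
})
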