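test_that("noise-free single exponential is recovered to high accuracy", {
  t <- log_time_grid(1e-5, 0.1, 200)
  tr <- cco_trace(445, t, 0.07 * exp(-t / 5e-3) + 0.002)
  fit <- fit_multiexponential(tr, 1)
  expect_true(fit$converged)
  expect_equal(fit$components$tau, 5e-3, tolerance = 1e-4)
  expect_equal(fit$components$amplitude, 0.07, tolerance = 1e-4)
  expect_equal(fit$offset, 0.002, tolerance = 1e-5)
})

test_that("noise-free three-exponential burst is recovered within 1%", {
  # the canonical phase pattern: 30 us, 100 us, 5 ms
  t <- log_time_grid(2e-6, 0.1, 400)
  taus <- c(30e-6, 100e-6, 5e-3)
  amps <- c(0.05, -0.02, 0.07)
  y <- 0.001 + amps[1] * exp(-t / taus[1]) + amps[2] * exp(-t / taus[2]) +
    amps[3] * exp(-t / taus[3])
  fit <- fit_multiexponential(cco_trace(445, t, y), 3)
  expect_equal(fit$components$tau, taus, tolerance = 0.01)
  expect_equal(fit$components$amplitude, amps, tolerance = 0.01)
})

test_that("fits are bit-identical under the same seed", {
  cfg <- flash_trace_config(times = log_time_grid(1e-6, 0.1, 200), seed = 11)
  tr <- generate_flash_traces(cfg)[["445"]]
  f1 <- fit_multiexponential(tr, 3, seed = 5)
  f2 <- fit_multiexponential(tr, 3, seed = 5)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$rss, f2$rss)
})

test_that("residual sigma tracks the injected noise level", {
  t <- log_time_grid(1e-5, 0.1, 300)
  set.seed(9)
  y <- 0.07 * exp(-t / 5e-3) + rnorm(length(t), sd = 0.002)
  fit <- fit_multiexponential(cco_trace(445, t, y), 1)
  expect_gt(fit$sigma, 0.002 * 0.85)
  expect_lt(fit$sigma, 0.002 * 1.15)
})

test_that("fit rejects unusable input", {
  t <- log_time_grid(1e-5, 0.1, 8)
  expect_error(fit_multiexponential(cco_trace(445, t, rnorm(8)), 2),
               class = "ccoflash_invalid_argument")
  tg50 <- log_time_grid(1e-5, 0.1, 50)
  expect_error(fit_multiexponential(cco_trace(445, tg50, rep(0.5, 50)), 1),
               class = "ccoflash_fit_failure")
  expect_error(fit_multiexponential(cco_trace(445, tg50, rnorm(50)), 1,
                                    tau_bounds = c(2, 1)),
               class = "ccoflash_invalid_argument")
  expect_error(fit_multiexponential(data.frame(x = 1), 1),
               class = "ccoflash_invalid_argument")
})

test_that("component extraction by nominal tau", {
  t <- log_time_grid(1e-5, 0.1, 300)
  y <- 0.05 * exp(-t / 30e-6) + 0.07 * exp(-t / 5e-3)
  fit <- fit_multiexponential(cco_trace(445, t, y), 2)
  expect_equal(component_amplitude(fit, 5e-3), 0.07, tolerance = 1e-3)
  expect_equal(component_amplitude(fit, 30e-6), 0.05, tolerance = 1e-3)
  # no component near 500 us
  expect_error(component_amplitude(fit, 5e-4, tolerance_factor = 2),
               class = "ccoflash_ambiguous_component")
  # huge window matches both -> ambiguous
  expect_error(component_amplitude(fit, 5e-4, tolerance_factor = 1000),
               class = "ccoflash_ambiguous_component")
  # phase_amplitude sums instead of failing
  expect_equal(phase_amplitude(fit, 5e-4, tolerance_factor = 1000), 0.12,
               tolerance = 1e-3)
  expect_true(is.na(phase_amplitude(fit, 5e-4, tolerance_factor = 2)))
})

test_that("amplitude_change sign convention", {
  expect_equal(amplitude_change(70, 60), 100 * 10 / 70)
  expect_equal(amplitude_change(60, 70), -100 / 6)
  expect_equal(amplitude_change(5, 5), 0)
  expect_error(amplitude_change(0, 1), class = "ccoflash_invalid_argument")
})

test_that("resolved_time_constants filters on amplitude-to-sigma ratio", {
  fake <- structure(
    list(components = data.frame(amplitude = c(0.05, 5e-4, -0.07),
                                 tau = c(1e-4, 1e-2, 5e-3)),
         sigma = 0.001,
         data = data.frame(time_s = c(1e-5, 0.1))),
    class = "fit_result")
  expect_equal(resolved_time_constants(fake, min_snr = 3), c(1e-4, 5e-3))
  expect_equal(resolved_time_constants(fake, min_snr = 0),
               c(1e-4, 5e-3, 1e-2))
  expect_equal(resolved_time_constants(fake, min_snr = 100), numeric(0))
  expect_error(resolved_time_constants(list(), 3),
               class = "ccoflash_invalid_argument")

  # a large-amplitude component with tau beyond the observation window
  # is degenerate with the offset, not a resolved phase
  fake2 <- fake
  fake2$components <- data.frame(amplitude = c(0.07, -0.006),
                                 tau = c(5e-3, 0.2))
  expect_equal(resolved_time_constants(fake2, min_snr = 3), 5e-3)
  expect_equal(resolved_time_constants(fake2, min_snr = 3, max_tau = Inf),
               c(5e-3, 0.2))

  # on real data the dominant 5-ms phase always survives the filter
  t <- log_time_grid(1e-5, 0.1, 300)
  set.seed(3)
  y <- 0.07 * exp(-t / 5e-3) + rnorm(length(t), sd = 0.002)
  fit <- fit_multiexponential(cco_trace(445, t, y), 3, seed = 2)
  res <- resolved_time_constants(fit, min_snr = 3)
  expect_gte(length(res), 1L)
  expect_true(any(abs(res - 5e-3) / 5e-3 < 0.25))
})

test_that("level_difference gives a model-free amplitude", {
  t <- log_time_grid(1e-5, 0.1, 300)
  y <- 0.07 * exp(-t / 5e-3) + 0.001
  tr <- cco_trace(445, t, y)
  d <- level_difference(tr, c(1e-5, 1e-4), c(0.05, 0.1))
  expect_equal(d, 0.07, tolerance = 0.02)
  expect_error(level_difference(tr, c(1, 2), c(3, 4)),
               class = "ccoflash_invalid_argument")
})

test_that("bootstrap gives small uncertainties on a clean trace", {
  t <- log_time_grid(1e-5, 0.1, 200)
  set.seed(8)
  y <- 0.07 * exp(-t / 5e-3) + rnorm(length(t), sd = 5e-4)
  fit <- fit_multiexponential(cco_trace(445, t, y), 1)
  bt <- bootstrap_fit(fit, n_boot = 20, seed = 4)
  expect_equal(dim(bt$replicates), c(20L, 3L))
  expect_lt(bt$sd[["amplitude1"]], 0.01 * 0.07 * 5)
  expect_lt(bt$sd[["tau1"]] / 5e-3, 0.05)
})
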