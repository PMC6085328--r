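test_that("default epsilon table reproduces the component bookkeeping", {
  eps <- default_epsilon_table()
  e445 <- setNames(subset(eps, wavelength_nm == 445)$epsilon,
                   subset(eps, wavelength_nm == 445)$state)
  e605 <- setNames(subset(eps, wavelength_nm == 605)$epsilon,
                   subset(eps, wavelength_nm == 605)$state)
  expect_equal(unname(e445["R"]), 150)   # heme a 60 = 40% of total
  expect_equal(unname(e445["F"]), 70)    # heme a 60 + site 10
  expect_equal(unname(e445["F_R"]), 10)
  expect_equal(unname(e445["O"]), 0)
  expect_equal(unname(e605["R"]), 100)
  expect_equal(unname(e605["F"]), 84)    # heme a 80 + 5% site share
  expect_equal(unname(e605["O"]), 0)
  # P_R and F are spectrally identical at 445 nm (plateau shape)
  expect_equal(unname(e445["P_R"]), unname(e445["F"]))
})

test_that("f_a scales the heme-a contribution", {
  eps <- default_epsilon_table(f_a = 0.5)
  e445 <- setNames(subset(eps, wavelength_nm == 445)$epsilon,
                   subset(eps, wavelength_nm == 445)$state)
  expect_equal(unname(e445["F"]), 0.5 * 60 + 10)
  expect_error(default_epsilon_table(f_a = 1.5),
               class = "ccoflash_invalid_argument")
})

test_that("epsilon table validation enforces the O reference", {
  tab <- data.frame(state = c("X", "O"), wavelength_nm = 445,
                    epsilon = c(10, 1))
  expect_error(epsilon_table(tab), class = "ccoflash_invalid_argument")
  tab$epsilon <- c(10, 0)
  expect_s3_class(epsilon_table(tab), "epsilon_table")
})

test_that("absorbance projection is exact Beer-Lambert", {
  # hand-built two-point trajectory
  occ <- rbind(c(R = 1, A = 0, P_R = 0, F = 0, F_R = 0, O = 0),
               c(R = 0, A = 0, P_R = 0, F = 1, F_R = 0, O = 0))
  traj <- population_trajectory(c(1e-6, 1e-3), occ)
  tr <- populations_to_absorbance(traj, default_epsilon_table(), 445,
                                  enzyme_conc = 2e-3, path = 0.5)
  expect_s3_class(tr, "cco_trace")
  expect_equal(tr$delta_a, 0.5 * 2e-3 * c(150, 70))
  tr605 <- populations_to_absorbance(traj, default_epsilon_table(), 605,
                                     enzyme_conc = 1e-3)
  expect_equal(tr605$delta_a, 1e-3 * c(100, 84))
})

test_that("projection rejects untabulated wavelengths/states", {
  occ <- cbind(X = c(1, 0), Y = c(0, 1))
  traj <- population_trajectory(c(1, 2), occ)
  expect_error(populations_to_absorbance(traj, default_epsilon_table(), 445),
               class = "ccoflash_config_error")
  K <- build_rate_matrix(default_cco_scheme(), 0.5e-3)
  traj2 <- solve_populations(K, times = c(1e-6, 1e-3))
  expect_error(populations_to_absorbance(traj2, default_epsilon_table(), 550),
               class = "ccoflash_config_error")
})

test_that("expected amplitude decrease reproduces the coefficient arithmetic", {
  expect_equal(expected_amplitude_decrease(60, 10), 100 * 10 / 70)
  expect_equal(expected_amplitude_decrease(60, 0), 0)
  expect_equal(expected_amplitude_decrease(0, 10), 100)
  expect_error(expected_amplitude_decrease(0, 0),
               class = "ccoflash_invalid_argument")
  expect_error(expected_amplitude_decrease(-1, 10),
               class = "ccoflash_invalid_argument")
})

test_that("cco_trace validates its inputs", {
  expect_error(cco_trace(445, c(1, 1), c(0, 0)),
               class = "ccoflash_invalid_argument")
  expect_error(cco_trace(445, c(1, 2), c(0, Inf)),
               class = "ccoflash_invalid_argument")
  tr <- cco_trace(445, c(1, 2), c(0.1, NA))
  expect_true(is.na(tr$delta_a[2]))  # NA allowed: blanked artifact
})
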