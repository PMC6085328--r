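test_that("populations conserve probability and reach the final state", {
  K <- build_rate_matrix(default_cco_scheme(), 0.5e-3)
  tg <- log_time_grid(1e-6, 0.1, 200)
  traj <- solve_populations(K, times = tg)
  expect_s3_class(traj, "population_trajectory")
  occ <- as.matrix(traj[-1])
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  expect_true(all(occ >= 0))
  expect_gt(traj$O[length(tg)], 0.99)
  # early: everything still in R
  expect_gt(traj$R[1], 0.9)
})

test_that("two-state chain matches the analytic solution", {
  K <- matrix(c(-3, 3, 0, 0), 2, 2,
              dimnames = list(c("X", "Y"), c("X", "Y")))
  t <- seq(0.01, 2, length.out = 50)
  traj <- solve_populations(K, times = t)
  expect_equal(traj$X, exp(-3 * t), tolerance = 1e-12)
  expect_equal(traj$Y, 1 - exp(-3 * t), tolerance = 1e-12)
})

test_that("matrix-exponential and ODE solvers agree on the default scheme", {
  for (pmfst in list(pmf_state(0, 0), pmf_state(100, 0.4))) {
    K <- build_rate_matrix(default_cco_scheme(), 0.5e-3, pmfst)
    tg <- log_time_grid(1e-6, 0.1, 100)
    a <- as.matrix(solve_populations(K, times = tg)[-1])
    b <- as.matrix(solve_populations_ode(K, times = tg)[-1])
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("solvers agree on 100 random chains (oracle property)", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    n <- sample(3:6, 1)
    states <- paste0("S", seq_len(n))
    # random unidirectional chain with rates over several decades
    tr <- data.frame(from = states[-n], to = states[-1],
                     k0 = 10^runif(n - 1, 0, 4),
                     o2_dependent = FALSE,
                     q = sample(0:1, n - 1, replace = TRUE))
    sch <- reaction_scheme(states, tr)
    K <- build_rate_matrix(sch, 1e-3,
                           pmf_state(runif(1, 0, 150), runif(1, 0, 0.5)))
    tg <- log_time_grid(1e-4, 10 / min(tr$k0), 40)
    a <- as.matrix(solve_populations(K, times = tg)[-1])
    b <- as.matrix(solve_populations_ode(K, times = tg)[-1])
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-6)
})

test_that("nearly degenerate rates trigger the expm fallback and stay exact", {
  # two equal rates make the eigenvector matrix defective
  sch <- reaction_scheme(
    c("X", "Y", "Z"),
    data.frame(from = c("X", "Y"), to = c("Y", "Z"),
               k0 = c(100, 100), o2_dependent = FALSE, q = 0))
  K <- build_rate_matrix(sch, 1e-3)
  t <- seq(0.001, 0.1, length.out = 30)
  traj <- solve_populations(K, times = t)
  # analytic: Erlang-2 occupancies
  expect_equal(traj$X, exp(-100 * t), tolerance = 1e-8)
  expect_equal(traj$Y, 100 * t * exp(-100 * t), tolerance = 1e-8)
})

test_that("custom initial conditions are honored", {
  K <- build_rate_matrix(default_cco_scheme(), 0.5e-3)
  p0 <- c(0, 0, 0, 1, 0, 0)  # start in F
  traj <- solve_populations(K, initial = p0, times = c(1e-6, 0.1))
  expect_equal(traj$F[1], 1, tolerance = 1e-3)
  expect_equal(traj$R, c(0, 0))
  expect_gt(traj$O[2], 0.99)
})

test_that("solver input validation", {
  K <- build_rate_matrix(default_cco_scheme(), 0.5e-3)
  expect_error(solve_populations(K, times = c(2, 1)),
               class = "ccoflash_invalid_argument")
  expect_error(solve_populations(K, initial = rep(0.5, 6), times = 1),
               class = "ccoflash_invalid_argument")
  bad <- matrix(c(-1, 2, 1, -2), 2, 2)  # columns do not sum to 0
  bad[1, 2] <- 5
  expect_error(solve_populations(bad, times = 1),
               class = "ccoflash_invalid_argument")
  expect_error(population_trajectory(c(1, 2),
                                     cbind(A = c(0.7, 0.7), B = c(0.1, 0.1))),
               class = "ccoflash_numerical_failure")
})
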