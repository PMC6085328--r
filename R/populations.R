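#' State-occupancy trajectory
#'
#' Container for solved state populations: a strictly increasing time
#' grid plus one occupancy column per state.  Occupancies at every time
#' point must lie in \[0, 1\] and sum to one (to within `tol`).
#'
#' @param times numeric vector of times in seconds, strictly increasing,
#'   all >= 0.
#' @param occupancy numeric matrix, `length(times)` rows, one column per
#'   state (column names are the state labels).
#' @param tol conservation tolerance.
#' @return An object of class `population_trajectory` (a data frame with
#'   column `time_s` followed by one column per state).
#' @export
population_trajectory <- function(times, occupancy, tol = 1e-8) {
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0) ||
      any(diff(times) <= 0)) {
    abort_invalid("`times` must be finite, >= 0 and strictly increasing")
  }
  occupancy <- as.matrix(occupancy)
  if (nrow(occupancy) != length(times) || is.null(colnames(occupancy))) {
    abort_invalid("`occupancy` must have one named column per state and one row per time")
  }
  if (any(!is.finite(occupancy))) {
    abort_numerical("non-finite occupancies in trajectory")
  }
  if (any(occupancy < -tol) || any(occupancy > 1 + tol)) {
    abort_numerical("occupancies outside [0, 1]")
  }
  dev <- max(abs(rowSums(occupancy) - 1))
  if (dev > tol) {
    abort_numerical(sprintf(
      "occupancies do not conserve probability (max deviation %.3g)", dev),
      max_deviation = dev)
  }
  out <- data.frame(time_s = times, occupancy, check.names = FALSE)
  class(out) <- c("population_trajectory", "data.frame")
  out
}

traj_states <- function(traj) setdiff(names(traj), "time_s")

traj_matrix <- function(traj) {
  as.matrix(traj[traj_states(traj)])
}

#' Solve state populations by matrix exponentiation
#'
#' Propagates the linear master equation `dp/dt = K p` exactly via the
#' eigendecomposition of the generator, `p(t) = V exp(L t) V^-1 p(0)`.
#' If the eigenvector matrix is ill-conditioned (nearly degenerate
#' rates), the solver falls back to scaling-and-squaring matrix
#' exponentials ([Matrix::expm()]) per output time, which is equally
#' exact.
#'
#' @param rate_matrix generator from [build_rate_matrix()] (any square
#'   probability-conserving generator is accepted).
#' @param initial initial occupancy vector (non-negative, sums to 1).
#'   Default: all population in the first state.
#' @param times strictly increasing output times in seconds, >= 0.
#' @return A [population_trajectory()].
#' @examples
#' K <- build_rate_matrix(default_cco_scheme(), 0.5e-3)
#' traj <- solve_populations(K, times = log_time_grid(1e-6, 0.1, 100))
#' tail(traj$O, 1)  # > 0.99: the chain finishes in O by 100 ms
#' @seealso [solve_populations_ode()] for the independent ODE cross-check.
#' @export
solve_populations <- function(rate_matrix, initial = NULL, times) {
  K <- validate_generator(rate_matrix)
  p0 <- validate_initial(initial, K)
  if (!is.numeric(times) || !length(times) || any(!is.finite(times)) ||
      any(times < 0) || any(diff(times) <= 0)) {
    abort_invalid("`times` must be finite, >= 0 and strictly increasing")
  }
  n <- nrow(K)
  eg <- eigen(K)
  V <- eg$vectors
  rc <- tryCatch(rcond(V), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-10) {
    c0 <- solve(V, if (is.complex(V)) as.complex(p0) else p0)
    occ <- t(vapply(times, function(tt) {
      Re(V %*% (exp(eg$values * tt) * c0))[, 1]
    }, numeric(n)))
  } else {
    # nearly defective generator: fall back to direct matrix exponentials
    occ <- t(vapply(times, function(tt) {
      as.numeric(Matrix::expm(Matrix::Matrix(K * tt)) %*% p0)
    }, numeric(n)))
  }
  if (any(!is.finite(occ))) {
    abort_numerical("population solve produced non-finite values",
                    rcond_eigenvectors = rc)
  }
  occ[occ < 0 & occ > -1e-12] <- 0
  colnames(occ) <- rownames(K)
  population_trajectory(times, occ)
}

#' Solve state populations by stiff ODE integration
#'
#' Numerically integrates the same master equation as
#' [solve_populations()] with [deSolve::lsoda()] at tight tolerances.
#' This routine exists as the independent cross-check (oracle) for the
#' matrix-exponential path; the two must agree to ~1e-6 absolute.
#'
#' @inheritParams solve_populations
#' @param rtol,atol integration tolerances passed to [deSolve::lsoda()].
#' @return A [population_trajectory()].
#' @export
solve_populations_ode <- function(rate_matrix, initial = NULL, times,
                                  rtol = 1e-10, atol = 1e-12) {
  K <- validate_generator(rate_matrix)
  p0 <- validate_initial(initial, K)
  if (!is.numeric(times) || !length(times) || any(!is.finite(times)) ||
      any(times < 0) || any(diff(times) <= 0)) {
    abort_invalid("`times` must be finite, >= 0 and strictly increasing")
  }
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  deriv <- function(t, y, parms) list(as.numeric(K %*% y))
  sol <- tryCatch(
    deSolve::lsoda(y = p0, times = tt, func = deriv, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 50000),
    warning = function(w) abort_numerical(
      sprintf("ODE integration failed: %s", conditionMessage(w))),
    error = function(e) abort_numerical(
      sprintf("ODE integration failed: %s", conditionMessage(e))))
  occ <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (prepend) occ <- occ[-1, , drop = FALSE]
  occ[occ < 0 & occ > -1e-9] <- 0
  colnames(occ) <- rownames(K)
  population_trajectory(times, occ, tol = 1e-7)
}

validate_generator <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K) || !is.numeric(K)) {
    abort_invalid("`rate_matrix` must be a square numeric matrix")
  }
  if (is.null(rownames(K))) {
    dimnames(K) <- list(paste0("S", seq_len(nrow(K))),
                        paste0("S", seq_len(nrow(K))))
  }
  offdiag <- K; diag(offdiag) <- 0
  if (any(offdiag < 0)) {
    abort_invalid("off-diagonal generator entries must be >= 0")
  }
  if (max(abs(colSums(K))) > 1e-8 * max(1, max(abs(K)))) {
    abort_invalid("generator columns must sum to zero")
  }
  unclass_matrix(K)
}

unclass_matrix <- function(K) {
  attr(K, "o2_conc_M") <- NULL
  attr(K, "pmf_state") <- NULL
  attr(K, "class") <- NULL
  K
}

validate_initial <- function(initial, K) {
  n <- nrow(K)
  if (is.null(initial)) {
    initial <- c(1, rep(0, n - 1))
  }
  if (length(initial) != n || any(!is.finite(initial)) || any(initial < 0)) {
    abort_invalid("`initial` must be a non-negative vector matching the states")
  }
  if (abs(sum(initial) - 1) > 1e-9) {
    abort_invalid("`initial` must sum to 1")
  }
  setNames(as.numeric(initial), rownames(K))
}
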