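#' Reaction scheme for the oxidative phase of the CytcO cycle
#'
#' A reaction scheme is an ordered set of microstate labels plus a table
#' of first-order transitions between them.  Each transition carries a
#' base rate constant `k0` (s^-1, or M^-1 s^-1 when `o2_dependent` is
#' set, in which case the rate is multiplied by the O2 concentration at
#' matrix-build time) and an effective electrogenic charge `q >= 0` used
#' by [scale_rate_for_pmf()].
#'
#' @param states character vector of distinct microstate labels, in
#'   kinetic order.
#' @param transitions data frame with columns `from`, `to`, `k0`,
#'   `o2_dependent` (logical) and `q`.
#' @return An object of class `reaction_scheme`.
#' @seealso [default_cco_scheme()] for the standard six-state chain.
#' @export
reaction_scheme <- function(states, transitions) {
  if (!is.character(states) || length(states) < 2L || anyDuplicated(states)) {
    abort_invalid("`states` must be >= 2 distinct labels")
  }
  req <- c("from", "to", "k0", "o2_dependent", "q")
  if (!is.data.frame(transitions) || !all(req %in% names(transitions))) {
    abort_invalid(sprintf("`transitions` must have columns %s",
                          paste(req, collapse = ", ")))
  }
  transitions <- as.data.frame(transitions)[req]
  bad <- setdiff(c(transitions$from, transitions$to), states)
  if (length(bad)) {
    abort_config(sprintf("transition references undeclared state(s): %s",
                         paste(unique(bad), collapse = ", ")))
  }
  if (any(transitions$from == transitions$to)) {
    abort_invalid("self-transitions are not allowed")
  }
  if (!is.numeric(transitions$k0) || any(!is.finite(transitions$k0)) ||
      any(transitions$k0 <= 0)) {
    abort_invalid("all base rates `k0` must be strictly positive")
  }
  if (!is.numeric(transitions$q) || any(!is.finite(transitions$q)) ||
      any(transitions$q < 0)) {
    abort_invalid("all electrogenic charges `q` must be >= 0")
  }
  transitions$o2_dependent <- as.logical(transitions$o2_dependent)
  if (anyNA(transitions$o2_dependent)) {
    abort_invalid("`o2_dependent` must be logical")
  }
  structure(list(states = states, transitions = transitions),
            class = "reaction_scheme")
}

#' Default six-state oxidative-phase scheme
#'
#' The unidirectional chain R -> A -> P_R -> F -> F_R -> O.  Base rates
#' correspond to the canonical time constants of the oxidative burst in
#' sub-mitochondrial particles: O2 binding with `k2 = 1e8 M^-1 s^-1`
#' (tau = 10 us at 1 mM O2), P_R formation in ~30 us, F formation in
#' 100 us at pH 7, F -> F_R electron transfer in 5 ms (the observed
#' membrane-bound value), and F_R -> O proton uptake ten times faster
#' than its formation so that, without a membrane potential, F -> O
#' appears as a single ~5-ms phase.
#'
#' Only the F_R -> O proton-uptake step is electrogenic by default
#' (`q = 1`); electron transfer from heme a to Cu_B runs parallel to the
#' membrane plane and carries `q = 0`.  Users exploring proton loading
#' during F -> F_R instead can re-assign `q` via the arguments.
#'
#' @param k_r_a second-order O2-binding rate, M^-1 s^-1.
#' @param k_a_pr,k_pr_f,k_f_fr,k_fr_o first-order base rates, s^-1.
#' @param q_r_a,q_a_pr,q_pr_f,q_f_fr,q_fr_o effective electrogenic
#'   charges per step.
#' @return A `reaction_scheme`.
#' @examples
#' default_cco_scheme()
#' @export
default_cco_scheme <- function(k_r_a = 1e8,
                               k_a_pr = 1 / 30e-6,
                               k_pr_f = 1e4,
                               k_f_fr = 200,
                               k_fr_o = 2000,
                               q_r_a = 0, q_a_pr = 0, q_pr_f = 0,
                               q_f_fr = 0, q_fr_o = 1) {
  states <- c("R", "A", "P_R", "F", "F_R", "O")
  transitions <- data.frame(
    from = states[-6],
    to = states[-1],
    k0 = c(k_r_a, k_a_pr, k_pr_f, k_f_fr, k_fr_o),
    o2_dependent = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    q = c(q_r_a, q_a_pr, q_pr_f, q_f_fr, q_fr_o))
  reaction_scheme(states, transitions)
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat(sprintf("<reaction_scheme> %d states: %s\n",
              length(x$states), paste(x$states, collapse = " -> ")))
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Rate (generator) matrix for a reaction scheme
#'
#' Assembles the master-equation generator `K` of a scheme at a given O2
#' concentration and membrane energization: `dp/dt = K p`.  O2-dependent
#' transitions use [pseudo_first_order_rate()]; every transition is then
#' scaled by [scale_rate_for_pmf()] with its own charge `q`.  Columns of
#' `K` sum to zero (probability conservation) and off-diagonal entries
#' are non-negative.
#'
#' @param scheme a [reaction_scheme()].
#' @param o2_conc dissolved O2 concentration in M (> 0).
#' @param pmf_state a [pmf_state()]; defaults to a de-energized membrane.
#' @return An object of class `rate_matrix`: the generator with
#'   `dimnames` equal to the state labels, and attributes `o2_conc_M`
#'   and `pmf_state`.
#' @examples
#' K <- build_rate_matrix(default_cco_scheme(), o2_conc = 0.5e-3)
#' colSums(K)  # all zero
#' @export
build_rate_matrix <- function(scheme, o2_conc, pmf_state = NULL) {
  if (!inherits(scheme, "reaction_scheme")) {
    abort_invalid("`scheme` must be a reaction_scheme")
  }
  check_number(o2_conc, "o2_conc", lower = 0, strict_lower = TRUE)
  if (is.null(pmf_state)) pmf_state <- ccoflash::pmf_state(0, 0)
  if (!inherits(pmf_state, "pmf_state")) {
    abort_invalid("`pmf_state` must be built with pmf_state()")
  }
  n <- length(scheme$states)
  K <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    k <- if (tr$o2_dependent[i]) {
      pseudo_first_order_rate(tr$k0[i], o2_conc)
    } else {
      tr$k0[i]
    }
    k <- scale_rate_for_pmf(k, tr$q[i], pmf_state$pmf_mV,
                            pmf_state$temperature_K)
    K[tr$to[i], tr$from[i]] <- K[tr$to[i], tr$from[i]] + k
    K[tr$from[i], tr$from[i]] <- K[tr$from[i], tr$from[i]] - k
  }
  structure(K, class = c("rate_matrix", "matrix"),
            o2_conc_M = o2_conc, pmf_state = pmf_state)
}
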