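#' Build the per-cycle transition matrix of a one-arm model
#'
#' Row composition rules:
#' \itemize{
#' \item Survival: the listed outgoing probabilities (Dead, Infection,
#'   RenalFailure, and for the HTx arm MCS) with the residual mass as a
#'   Survival self-loop.
#' \item Complication states (Infection, RenalFailure): the recurrence
#'   probability as a self-loop, the arm's background mortality
#'   (Survival to Dead) to Dead, and the remainder back to Survival —
#'   complications count as survival, so patients who neither recur nor
#'   die return to the well state.
#' \item MCS (HTx arm only): the listed return-to-Survival probability,
#'   background mortality to Dead, residual mass stays on support.
#' \item Dead: absorbing.
#' }
#'
#' @param spec A `model_spec` from [assemble_model()].
#' @return Square matrix with `spec$states` dimnames; rows sum to 1.
#' @export
build_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  states <- spec$states
  tr <- spec$transitions
  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  p <- function(f, t) {
    i <- which(tr$from == f & tr$to == t)
    if (length(i)) sum(tr$mean[i]) else 0
  }
  p_dead <- p("Survival", "Dead")

  for (to in setdiff(states, "Survival")) P["Survival", to] <- p("Survival", to)
  P["Survival", "Survival"] <- 1 - sum(P["Survival", ])

  for (s in intersect(c("Infection", "RenalFailure"), states)) {
    P[s, s] <- p(s, s)
    P[s, "Dead"] <- p_dead
    P[s, "Survival"] <- 1 - P[s, s] - p_dead
  }
  if ("MCS" %in% states) {
    P["MCS", "Survival"] <- p("MCS", "Survival")
    P["MCS", "Dead"] <- p_dead
    P["MCS", "MCS"] <- 1 - P["MCS", "Survival"] - p_dead
  }
  P["Dead", "Dead"] <- 1

  if (any(P < -1e-12))
    stopf("transition row mass exceeds 1 after composition (state %s)",
          states[which(apply(P, 1, min) < -1e-12)[1]])
  P[P < 0] <- 0
  if (any(abs(rowSums(P) - 1) > 1e-12)) stopf("transition rows must sum to 1")
  P
}

#' Run a Markov cohort through a transition matrix
#'
#' @param P Transition matrix (rows sum to 1).
#' @param initial_distribution State-occupancy fractions at cycle 0;
#'   must sum to 1. Both arms start with the full cohort in Survival.
#' @param n_cycles Number of cycles to simulate (>= 1).
#' @return A `(n_cycles + 1) x n_states` occupancy matrix of class
#'   `cohort_trace`; row `k + 1` is the distribution at cycle boundary `k`.
#' @export
run_cohort <- function(P, initial_distribution, n_cycles) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stopf("P must be a square matrix")
  if (length(initial_distribution) != nrow(P))
    stopf("initial distribution length %d does not match %d states",
          length(initial_distribution), nrow(P))
  assert_prob_vector(initial_distribution, "initial_distribution", tol = 1e-12)
  assert_number(n_cycles, "n_cycles", lower = 1)
  trace <- matrix(0, n_cycles + 1L, nrow(P),
                  dimnames = list(0:n_cycles, rownames(P)))
  trace[1L, ] <- initial_distribution
  for (k in seq_len(n_cycles)) trace[k + 1L, ] <- trace[k, ] %*% P
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' Discounted, half-cycle-corrected costs and QALYs of a cohort trace
#'
#' Transitions are taken to occur at cycle midpoints, so cycle `k`
#' (k = 0, 1, ...) accrues payoffs against the trapezoidal occupancy
#' \eqn{\tfrac12(\mathrm{occ}_k + \mathrm{occ}_{k+1})}, discounted by
#' \eqn{(1+r)^{-k}}. One-time entry costs (the transplant admission) are
#' charged undiscounted at cycle 0 in proportion to the initial occupancy
#' of their entry state. Cumulative totals are reported at each horizon in
#' `spec$report_horizons`.
#'
#' @param trace A `cohort_trace` covering at least `horizon` cycles.
#' @param spec The `model_spec` that produced the trace.
#' @return An `arm_result`: list with `arm`, `horizons` (data frame
#'   `horizon`, `cost`, `qaly`), and the `trace`.
#' @export
discounted_payoffs <- function(trace, spec) {
  stopifnot(inherits(spec, "model_spec"))
  states <- spec$states
  if (!identical(colnames(trace), states))
    stopf("trace states do not match the model spec")
  n_cycles <- nrow(trace) - 1L
  horizons <- spec$report_horizons
  cyc <- horizons / spec$cycle_length
  if (any(abs(cyc - round(cyc)) > 1e-9)) stopf("report horizons must be whole cycles")
  cyc <- as.integer(round(cyc))
  if (max(cyc) > n_cycles) stopf("horizon %g y exceeds the %d-cycle trace",
                                 max(horizons), n_cycles)

  cvec <- uvec <- stats::setNames(numeric(length(states)), states)
  percyc <- spec$costs[spec$costs$type == "per_cycle", ]
  cvec[percyc$state] <- percyc$mean
  uvec[spec$utilities$state] <- spec$utilities$mean
  cvec["Dead"] <- uvec["Dead"] <- 0

  onetime <- spec$costs[spec$costs$type == "one_time", ]
  entry_cost <- if (nrow(onetime))
    sum(onetime$mean * trace[1L, onetime$state]) else 0

  k <- seq_len(max(cyc)) - 1L                   # cycles 0 .. max-1
  disc <- (1 + spec$discount_rate)^(-k)
  w <- 0.5 * (trace[k + 1L, , drop = FALSE] + trace[k + 2L, , drop = FALSE])
  cost_k <- as.numeric(w %*% cvec) * disc
  qaly_k <- as.numeric(w %*% uvec) * disc * spec$cycle_length

  res <- data.frame(horizon = horizons,
                    cost = entry_cost + vapply(cyc, function(m) sum(cost_k[seq_len(m)]), 0),
                    qaly = vapply(cyc, function(m) sum(qaly_k[seq_len(m)]), 0))
  structure(list(arm = spec$arm, horizons = res, trace = trace), class = "arm_result")
}

#' Run one arm end-to-end: matrix, trace, discounted payoffs
#'
#' @param spec A `model_spec`.
#' @return An `arm_result`; the cohort starts fully in Survival.
#' @export
run_arm <- function(spec) {
  P <- build_transition_matrix(spec)
  init <- stats::setNames(as.numeric(spec$states == "Survival"), spec$states)
  n_cycles <- as.integer(round(spec$horizon / spec$cycle_length))
  discounted_payoffs(run_cohort(P, init, n_cycles), spec)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s — discounted totals:\n", x$arm))
  print(transform(x$horizons, cost = round(cost, 2), qaly = round(qaly, 4)),
        row.names = FALSE)
  invisible(x)
}
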