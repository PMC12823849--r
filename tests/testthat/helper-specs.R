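# builders for custom model specs and independent payoff oracles

make_params <- function(arm, transitions, costs, utilities,
                        cycle_length = 1, horizon = 10, discount_rate = 0.05,
                        report_horizons = c(1, 5, 10)) {
  sec <- function(x) stats::setNames(list(x), arm)
  list(transitions = sec(transitions), costs = sec(costs),
       utilities = sec(utilities),
       settings = list(cycle_length = cycle_length, horizon = horizon,
                       discount_rate = discount_rate,
                       report_horizons = report_horizons,
                       gdp_per_capita = 89358, currency_year = 2023))
}

trans_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(from = r[[1]], to = r[[2]], mean = as.numeric(r[[3]]),
               ci_low = as.numeric(if (length(r) >= 4) r[[4]] else r[[3]]),
               ci_high = as.numeric(if (length(r) >= 5) r[[5]] else r[[3]]))))
}

cost_df <- function(states, means, onetime = NULL, q_spread = c(0.9, 1.1)) {
  rows <- data.frame(label = states, type = "per_cycle", state = states,
                     mean = means, q1 = means * q_spread[1],
                     q3 = means * q_spread[2], source_year = 2023)
  if (!is.null(onetime))
    rows <- rbind(data.frame(label = "admission", type = "one_time",
                             state = "Survival", mean = onetime,
                             q1 = onetime * q_spread[1],
                             q3 = onetime * q_spread[2], source_year = 2023),
                  rows)
  rows
}

util_df <- function(states, means, half = 0) {
  data.frame(state = states, mean = means,
             ci_low = pmax(means - half, 0), ci_high = pmin(means + half, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-alive-state model: Survival -> Dead with probability p per cycle
one_state_spec <- function(p_dead, cost, utility, discount_rate = 0.05,
                           horizon = 10, onetime = NULL) {
  assemble_model("tMCS", make_params(
    "tMCS",
    trans_df(list("Survival", "Dead", p_dead)),
    cost_df("Survival", cost, onetime = onetime),
    util_df("Survival", utility),
    discount_rate = discount_rate, horizon = horizon,
    report_horizons = horizon))
}

# random valid 5-state HTx-style model for engine equivalence checks
random_spec <- function(seed) {
  set.seed(seed)
  d <- runif(1, 0.01, 0.15)
  out <- runif(3, 0.05, 0.25)          # Infection, RenalFailure, MCS
  rec <- runif(2, 0.05, 1 - d - 0.05)  # complication recurrences
  ret <- runif(1, 0.1, 1 - d - 0.05)   # MCS -> Survival
  tr <- trans_df(
    list("Survival", "Dead", d),
    list("Survival", "Infection", out[1]),
    list("Infection", "Infection", rec[1]),
    list("Survival", "RenalFailure", out[2]),
    list("RenalFailure", "RenalFailure", rec[2]),
    list("Survival", "MCS", out[3]),
    list("MCS", "Survival", ret))
  states <- c("Survival", "Infection", "RenalFailure", "MCS")
  assemble_model("HTx", make_params(
    "HTx", tr,
    cost_df(states, runif(4, 1e3, 1e5), onetime = runif(1, 1e4, 3e5)),
    util_df(states, runif(4, 0.2, 0.95)),
    discount_rate = runif(1, 0, 0.1)))
}

# independent brute-force accumulation over a trace, written as explicit
# per-cycle scalar loops (no matrix algebra shared with the engine)
oracle_payoffs <- function(spec, trace) {
  r <- spec$discount_rate
  horizons <- spec$report_horizons
  per_cost <- list(); per_util <- list()
  for (i in seq_len(nrow(spec$costs)))
    if (spec$costs$type[i] == "per_cycle")
      per_cost[[spec$costs$state[i]]] <- spec$costs$mean[i]
  for (i in seq_len(nrow(spec$utilities)))
    per_util[[spec$utilities$state[i]]] <- spec$utilities$mean[i]
  entry <- 0
  for (i in seq_len(nrow(spec$costs)))
    if (spec$costs$type[i] == "one_time")
      entry <- entry + spec$costs$mean[i] * trace[1, spec$costs$state[i]]
  out <- data.frame(horizon = horizons, cost = NA_real_, qaly = NA_real_)
  for (h in seq_along(horizons)) {
    n_cyc <- as.integer(horizons[h] / spec$cycle_length)
    total_cost <- entry; total_qaly <- 0
    for (k in 0:(n_cyc - 1)) {
      disc <- (1 + r)^(-k)
      for (s in spec$states) {
        occ <- (trace[k + 1, s] + trace[k + 2, s]) / 2
        if (!is.null(per_cost[[s]])) total_cost <- total_cost + occ * per_cost[[s]] * disc
        if (!is.null(per_util[[s]]))
          total_qaly <- total_qaly + occ * per_util[[s]] * disc * spec$cycle_length
      }
    }
    out$cost[h] <- total_cost; out$qaly[h] <- total_qaly
  }
  out
}

# hand construction of a psa_samples object for counting oracles
fake_psa_samples <- function(delta_cost, delta_qaly, wtp_grid = c(0, 1, 2, 3, 4)) {
  structure(list(samples = data.frame(iteration = seq_along(delta_cost),
                                      delta_cost = delta_cost,
                                      delta_qaly = delta_qaly),
                 draws = NULL, parameters = NULL, n_resampled = 0L,
                 config = structure(list(n_iterations = length(delta_cost),
                                         seed = 1, wtp_grid = wtp_grid),
                                    class = "psa_config")),
            class = "psa_samples")
}

# fake propensity fit with chosen scores
fake_fit <- function(treated_scores, control_scores) {
  t_ids <- sprintf("T%02d", seq_along(treated_scores))
  c_ids <- sprintf("C%02d", seq_along(control_scores))
  scores <- c(stats::setNames(treated_scores, t_ids),
              stats::setNames(control_scores, c_ids))
  structure(list(coefficients = NULL, vcov = NULL, scores = scores,
                 treated = stats::setNames(c(rep(TRUE, length(t_ids)),
                                             rep(FALSE, length(c_ids))),
                                           names(scores)),
                 converged = TRUE, n_iterations = 1L, separation = FALSE,
                 dropped = character()),
            class = "propensity_fit")
}
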