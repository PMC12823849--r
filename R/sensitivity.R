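#' Uncertain-parameter catalog of a two-arm model
#'
#' Enumerates every uncertain parameter of both arm specs — transition
#' probabilities (95% CI bounds), per-state and one-time costs (quartile
#' bounds), and state utilities (95% CI bounds) — with the fitted PSA
#' distribution for each: beta for probabilities and utilities
#' (moment-matched via [beta_from_mean_ci()]), gamma for costs (quartile-
#' matched via [gamma_from_quartiles()]). Zero-width bounds yield a
#' degenerate (point-mass) entry.
#'
#' @param spec_a,spec_b `model_spec`s for the two arms.
#' @return Data frame with `parameter`, `arm`, `kind`, `index`, `point`,
#'   `low`, `high`, `sd` (analytic SD of the fitted distribution), plus a
#'   `draw` list-column of sampling functions.
#' @export
psa_parameters <- function(spec_a, spec_b) {
  one_spec <- function(spec) {
    tr <- spec$transitions; co <- spec$costs; ut <- spec$utilities
    rows <- list()
    add <- function(parameter, kind, index, point, low, high) {
      rows[[length(rows) + 1L]] <<- data.frame(
        parameter = parameter, arm = spec$arm, kind = kind, index = index,
        point = point, low = low, high = high)
    }
    for (i in seq_len(nrow(tr)))
      add(sprintf("%s prob %s->%s", spec$arm, tr$from[i], tr$to[i]),
          "transition", i, tr$mean[i], tr$ci_low[i], tr$ci_high[i])
    for (i in seq_len(nrow(co)))
      add(sprintf("%s cost %s", spec$arm, co$label[i]),
          "cost", i, co$mean[i], co$q1[i], co$q3[i])
    for (i in seq_len(nrow(ut)))
      add(sprintf("%s utility %s", spec$arm, ut$state[i]),
          "utility", i, ut$mean[i], ut$ci_low[i], ut$ci_high[i])
    do.call(rbind, rows)
  }
  catalog <- rbind(one_spec(spec_a), one_spec(spec_b))

  fit_one <- function(kind, point, low, high) {
    if (high - low < 1e-12)
      return(list(sd = 0, draw = local({ p <- point; function(n) rep(p, n) })))
    if (kind == "cost") {
      f <- gamma_from_quartiles(low, high)
      list(sd = sqrt(f$shape) * f$scale,
           draw = local({ f <- f; function(n) stats::rgamma(n, shape = f$shape, scale = f$scale) }))
    } else {
      f <- beta_from_mean_ci(point, low, high)
      s <- f$shape1 + f$shape2
      list(sd = sqrt(f$shape1 * f$shape2 / (s^2 * (s + 1))),
           draw = local({ f <- f; function(n) stats::rbeta(n, f$shape1, f$shape2) }))
    }
  }
  fits <- Map(fit_one, catalog$kind, catalog$point, catalog$low, catalog$high)
  catalog$sd <- vapply(fits, `[[`, numeric(1), "sd")
  catalog$draw <- lapply(fits, `[[`, "draw")
  catalog
}

# write a parameter value into a spec (means only; bounds untouched)
spec_set_param <- function(spec, kind, index, value) {
  switch(kind,
         transition = { spec$transitions$mean[index] <- value },
         cost = { spec$costs$mean[index] <- value },
         utility = { spec$utilities$mean[index] <- value },
         stopf("unknown parameter kind: %s", kind))
  spec
}

# deltas (a - b) at `horizon` after perturbation; NULL if the perturbed
# model is structurally invalid (row mass > 1)
perturbed_deltas <- function(spec_a, spec_b, horizon) {
  out <- try({
    d <- incremental(run_arm(spec_a), run_arm(spec_b), horizon)
    list(delta_cost = d[["delta_cost"]], delta_qaly = d[["delta_qaly"]])
  }, silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

#' One-way deterministic sensitivity analysis (INMB tornado)
#'
#' Each uncertain parameter is set in turn to its low and high bound
#' (95% CI for probabilities and utilities, quartiles for costs) with all
#' others at their point estimates; both arms are re-run and the INMB at
#' the reference willingness-to-pay recomputed. Entries are sorted by
#' descending INMB range. Bounds that make a transition row exceed unit
#' mass are skipped with a diagnostic.
#'
#' @param spec_a,spec_b `model_spec`s (intervention, comparator).
#' @param wtp_ref Reference WTP (RMB/QALY); default 1x GDP per capita.
#' @param horizon Report horizon (years).
#' @return List with `entries` (data frame: `parameter`, `low_value`,
#'   `high_value`, `inmb_low`, `inmb_high`, `range`), `wtp_ref`,
#'   `inmb_base`, and `skipped` (parameter names).
#' @export
one_way_dsa <- function(spec_a, spec_b, wtp_ref = spec_a$gdp_per_capita,
                        horizon = 10) {
  assert_number(wtp_ref, "wtp_ref", lower = 0)
  catalog <- psa_parameters(spec_a, spec_b)
  base <- perturbed_deltas(spec_a, spec_b, horizon)
  if (is.null(base)) stopf("base-case model is invalid")

  eval_bound <- function(row, value) {
    sa <- spec_a; sb <- spec_b
    if (row$arm == spec_a$arm) sa <- spec_set_param(sa, row$kind, row$index, value)
    else sb <- spec_set_param(sb, row$kind, row$index, value)
    d <- perturbed_deltas(sa, sb, horizon)
    if (is.null(d)) NA_real_ else inmb(d$delta_cost, d$delta_qaly, wtp_ref)
  }
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    data.frame(parameter = row$parameter, low_value = row$low, high_value = row$high,
               inmb_low = eval_bound(row, row$low),
               inmb_high = eval_bound(row, row$high))
  })
  entries <- do.call(rbind, rows)
  skipped <- entries$parameter[is.na(entries$inmb_low) | is.na(entries$inmb_high)]
  entries <- entries[!entries$parameter %in% skipped, ]
  entries$range <- abs(entries$inmb_high - entries$inmb_low)
  entries <- entries[order(-entries$range, entries$parameter), ]
  rownames(entries) <- NULL
  list(entries = entries, wtp_ref = wtp_ref,
       inmb_base = inmb(base$delta_cost, base$delta_qaly, wtp_ref),
       skipped = as.character(skipped))
}

#' Probabilistic sensitivity analysis configuration
#'
#' @param n_iterations Monte Carlo iterations (default 1,000).
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; default 0 to
#'   3x GDP per capita in 0.05-GDP steps (61 points).
#' @param gdp_per_capita GDP per capita used for the default grid.
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_iterations = 1000, seed = 1, wtp_grid = NULL,
                       gdp_per_capita = 89358) {
  assert_number(n_iterations, "n_iterations", lower = 1)
  if (is.null(wtp_grid))
    wtp_grid <- seq(0, 3 * gdp_per_capita, by = 0.05 * gdp_per_capita)
  if (length(wtp_grid) == 0L || wtp_grid[1] != 0 || is.unsorted(wtp_grid, strictly = TRUE))
    stopf("wtp_grid must start at 0 and increase strictly")
  structure(list(n_iterations = as.integer(n_iterations), seed = seed,
                 wtp_grid = wtp_grid), class = "psa_config")
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Each iteration draws every uncertain parameter independently from its
#' fitted distribution (beta for probabilities/utilities, gamma for
#' costs), rebuilds both arm models, re-runs the cohort engine, and
#' records the incremental cost and QALYs at `horizon`. Draws that
#' produce a structurally invalid model (transition row mass > 1) are
#' rejected and redrawn, with a count kept.
#'
#' @param spec_a,spec_b `model_spec`s (intervention, comparator).
#' @param config A [psa_config()].
#' @param horizon Report horizon (years).
#' @return A `psa_samples` object: `samples` (data frame `iteration`,
#'   `delta_cost`, `delta_qaly`), `draws` (iterations x parameters
#'   matrix), `parameters` (catalog without draw functions),
#'   `n_resampled`, and the `config`.
#' @export
sample_psa <- function(spec_a, spec_b, config = psa_config(), horizon = 10) {
  stopifnot(inherits(config, "psa_config"))
  catalog <- psa_parameters(spec_a, spec_b)
  n <- config$n_iterations
  set.seed(config$seed)
  draws <- matrix(NA_real_, n, nrow(catalog),
                  dimnames = list(NULL, catalog$parameter))
  dc <- dq <- numeric(n)
  n_resampled <- 0L

  idx_a <- which(catalog$arm == spec_a$arm)
  idx_b <- which(catalog$arm == spec_b$arm)
  apply_draw <- function(spec, rows, x) {
    for (k in c("transition", "cost", "utility")) {
      sel <- rows[catalog$kind[rows] == k]
      if (!length(sel)) next
      tgt <- switch(k, transition = "transitions", cost = "costs", utility = "utilities")
      col <- switch(k, transition = "mean", cost = "mean", utility = "mean")
      spec[[tgt]][[col]][catalog$index[sel]] <- x[sel]
    }
    spec
  }

  for (it in seq_len(n)) {
    repeat {
      x <- vapply(catalog$draw, function(f) f(1L), numeric(1))
      d <- perturbed_deltas(apply_draw(spec_a, idx_a, x),
                            apply_draw(spec_b, idx_b, x), horizon)
      if (!is.null(d)) break
      n_resampled <- n_resampled + 1L
    }
    draws[it, ] <- x
    dc[it] <- d$delta_cost
    dq[it] <- d$delta_qaly
  }
  structure(list(samples = data.frame(iteration = seq_len(n),
                                      delta_cost = dc, delta_qaly = dq),
                 draws = draws,
                 parameters = catalog[setdiff(names(catalog), "draw")],
                 n_resampled = n_resampled, config = config),
            class = "psa_samples")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA samples with
#' strictly positive INMB (ties count as not cost-effective).
#'
#' @param samples A `psa_samples` object.
#' @param wtp_grid WTP grid; defaults to the grid in the samples' config.
#' @return Data frame of class `ceac_curve` with `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = samples$config$wtp_grid) {
  stopifnot(inherits(samples, "psa_samples"))
  if (nrow(samples$samples) == 0L) stopf("no PSA samples")
  if (length(wtp_grid) == 0L) stopf("empty willingness-to-pay grid")
  s <- samples$samples
  prob <- vapply(wtp_grid,
                 function(l) mean(inmb(s$delta_cost, s$delta_qaly, l) > 0),
                 numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Smallest WTP at which the acceptability probability reaches a target
#'
#' @param curve A `ceac_curve`.
#' @param target_prob Target probability in [0, 1].
#' @return List with `reached` (logical) and `wtp` (grid value, or `NA`
#'   when the curve never reaches the target).
#' @export
wtp_at_probability <- function(curve, target_prob) {
  stopifnot(inherits(curve, "ceac_curve"))
  if (nrow(curve) == 0L) stopf("empty curve")
  assert_number(target_prob, "target_prob", lower = 0, upper = 1)
  i <- which(curve$probability >= target_prob)[1]
  if (is.na(i)) list(reached = FALSE, wtp = NA_real_)
  else list(reached = TRUE, wtp = curve$wtp[i])
}

#' Cost-effectiveness plane with quadrant labels
#'
#' @param samples A `psa_samples` object.
#' @return Data frame `delta_qaly`, `delta_cost`, `quadrant` (NE: more
#'   effective & costlier; SE: more effective & cheaper, i.e. dominant;
#'   NW: less effective & costlier, i.e. dominated; SW: less effective &
#'   cheaper). Axis points (zero deltas) are assigned to the
#'   non-negative side. `attr(, "quadrant_counts")` tabulates all four.
#' @export
ce_plane <- function(samples) {
  stopifnot(inherits(samples, "psa_samples"))
  s <- samples$samples
  if (nrow(s) == 0L) stopf("no PSA samples")
  quadrant <- ifelse(s$delta_qaly >= 0,
                     ifelse(s$delta_cost >= 0, "NE", "SE"),
                     ifelse(s$delta_cost >= 0, "NW", "SW"))
  out <- data.frame(delta_qaly = s$delta_qaly, delta_cost = s$delta_cost,
                    quadrant = factor(quadrant, levels = c("NE", "SE", "NW", "SW")))
  attr(out, "quadrant_counts") <- table(out$quadrant)
  out
}
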