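#' Incremental cost and effect between two arm results
#'
#' @param a,b `arm_result` objects (convention: `a` = BTT-tMCS, `b` = HTx,
#'   so positive deltas mean bridging costs more / yields more QALYs).
#' @param horizon Report horizon (years) present in both results.
#' @return Named vector `c(delta_cost, delta_qaly)` = a - b.
#' @export
incremental <- function(a, b, horizon) {
  row <- function(r) {
    i <- match(horizon, r$horizons$horizon)
    if (is.na(i)) stopf("arm %s does not report horizon %g", r$arm, horizon)
    r$horizons[i, ]
  }
  ra <- row(a); rb <- row(b)
  c(delta_cost = ra$cost - rb$cost, delta_qaly = ra$qaly - rb$qaly)
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost,delta_qaly Increments (intervention minus comparator).
#' @return List with `label` — one of `"icer"` (ratio meaningful),
#'   `"dominant"` (cheaper and more effective), `"dominated"` (costlier
#'   and less effective), `"undefined"` (zero effect difference) — and
#'   `value` (the ratio, or `NA` when not a ratio).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) return(list(label = "undefined", value = NA_real_))
  if (delta_cost < 0 && delta_qaly > 0) return(list(label = "dominant", value = NA_real_))
  if (delta_cost > 0 && delta_qaly < 0) return(list(label = "dominated", value = NA_real_))
  list(label = "icer", value = delta_cost / delta_qaly)
}

#' Incremental net monetary benefit
#'
#' \eqn{\mathrm{INMB}(\lambda) = \lambda \Delta E - \Delta C}.
#'
#' @param delta_cost,delta_qaly Increments.
#' @param wtp Willingness-to-pay threshold (RMB/QALY, >= 0).
#' @return INMB in RMB; positive favors the intervention.
#' @export
inmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stopf("willingness-to-pay must be >= 0")
  wtp * delta_qaly - delta_cost
}

#' WHO willingness-to-pay band from GDP per capita
#'
#' One to three times GDP per capita per QALY gained.
#'
#' @param gdp_per_capita GDP per capita (RMB, > 0); 2023 China: 89,358.
#' @return List with `gdp_per_capita`, `lower` (1x), `upper` (3x).
#' @export
who_thresholds <- function(gdp_per_capita = 89358) {
  assert_number(gdp_per_capita, "gdp_per_capita", lower = 0, strict_lower = TRUE)
  list(gdp_per_capita = gdp_per_capita,
       lower = gdp_per_capita, upper = 3 * gdp_per_capita)
}

#' Incremental cost-effectiveness table over report horizons
#'
#' @param a,b `arm_result` objects (intervention, comparator).
#' @param horizons Horizons to report; default those present in `a`.
#' @return A `cea_result` data frame: per horizon the arm costs/QALYs,
#'   increments, ICER value and label.
#' @export
cea_table <- function(a, b, horizons = a$horizons$horizon) {
  rows <- lapply(horizons, function(h) {
    d <- incremental(a, b, h)
    ic <- icer(d[["delta_cost"]], d[["delta_qaly"]])
    ia <- match(h, a$horizons$horizon); ib <- match(h, b$horizons$horizon)
    data.frame(horizon = h,
               cost_tMCS = a$horizons$cost[ia], cost_HTx = b$horizons$cost[ib],
               qaly_tMCS = a$horizons$qaly[ia], qaly_HTx = b$horizons$qaly[ib],
               delta_cost = d[["delta_cost"]], delta_qaly = d[["delta_qaly"]],
               icer = ic$value, icer_label = ic$label)
  })
  structure(do.call(rbind, rows), class = c("cea_result", "data.frame"))
}

#' Sex-subgroup cost-effectiveness table
#'
#' Runs the per-stratum models and lays out the published subgroup-table
#' shape: within-arm male-female contrasts and within-sex arm contrasts.
#'
#' @param specs Nested list `specs[[sex]][[arm]]` of `model_spec`s, with
#'   sexes `male`, `female` and arms `tMCS`, `HTx`.
#' @param horizon Report horizon (years).
#' @return List with `by_stratum` (cost/QALY per sex and arm),
#'   `male_vs_female` (per arm: deltas and ICER of male vs female), and
#'   `tmcs_vs_htx` (per sex: deltas and ICER of tMCS vs HTx).
#' @export
subgroup_cea <- function(specs, horizon = 10) {
  sexes <- c("male", "female")
  for (sx in sexes) for (arm in arm_levels)
    if (is.null(specs[[sx]][[arm]]))
      stopf("missing model spec for stratum %s/%s", sx, arm)
  res <- lapply(specs[sexes], function(by_arm) lapply(by_arm[arm_levels], run_arm))

  cell <- function(sx, arm) {
    r <- res[[sx]][[arm]]$horizons
    r[match(horizon, r$horizon), c("cost", "qaly")]
  }
  by_stratum <- do.call(rbind, lapply(sexes, function(sx)
    do.call(rbind, lapply(arm_levels, function(arm)
      cbind(data.frame(sex = sx, arm = arm), cell(sx, arm))))))

  contrast <- function(dc, dq) {
    ic <- icer(dc, dq)
    data.frame(delta_cost = dc, delta_qaly = dq,
               icer = ic$value, icer_label = ic$label)
  }
  male_vs_female <- do.call(rbind, lapply(arm_levels, function(arm) {
    m <- cell("male", arm); f <- cell("female", arm)
    cbind(data.frame(arm = arm), contrast(m$cost - f$cost, m$qaly - f$qaly))
  }))
  tmcs_vs_htx <- do.call(rbind, lapply(sexes, function(sx) {
    d <- incremental(res[[sx]]$tMCS, res[[sx]]$HTx, horizon)
    cbind(data.frame(sex = sx), contrast(d[["delta_cost"]], d[["delta_qaly"]]))
  }))
  list(by_stratum = by_stratum, male_vs_female = male_vs_female,
       tmcs_vs_htx = tmcs_vs_htx)
}
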