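#' Beta shapes from a mean and 95% confidence interval
#'
#' Moment-matches a beta distribution to a published point estimate with a
#' symmetric-normal 95% CI: the CI half-width is mapped to a standard
#' deviation through the normal 0.975 quantile, then
#' \eqn{\alpha = \mu(\mu(1-\mu)/\sigma^2 - 1)} and
#' \eqn{\beta = (1-\mu)(\mu(1-\mu)/\sigma^2 - 1)}. The fitted distribution's
#' analytic mean equals `mean` by construction.
#'
#' @param mean Point estimate, strictly inside (0, 1).
#' @param ci_low,ci_high 95% CI bounds with `ci_low < ci_high`.
#' @return A list with `shape1`, `shape2` for [stats::rbeta()].
#' @examples
#' beta_from_mean_ci(0.046, 0.039, 0.053)
#' @export
beta_from_mean_ci <- function(mean, ci_low, ci_high) {
  assert_number(mean, "mean", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(ci_low, "ci_low")
  assert_number(ci_high, "ci_high")
  if (ci_low >= ci_high) stopf("ci_low (%g) must be < ci_high (%g)", ci_low, ci_high)
  sd <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  v <- sd^2
  if (v >= mean * (1 - mean))
    stopf("beta infeasible: variance %.6g >= mean(1-mean) = %.6g", v, mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Gamma shape and scale from quartiles
#'
#' Root-finds the gamma shape whose interquartile ratio matches `q3/q1`,
#' then sets the scale so the 25th and 75th percentiles reproduce the
#' inputs. Used for cost parameters reported as Q1/Q3.
#'
#' @param q1,q3 Strictly positive quartiles with `q1 < q3`.
#' @return A list with `shape` and `scale`.
#' @examples
#' f <- gamma_from_quartiles(100, 200)
#' qgamma(c(0.25, 0.75), shape = f$shape, scale = f$scale)
#' @export
gamma_from_quartiles <- function(q1, q3) {
  assert_number(q1, "q1", lower = 0, strict_lower = TRUE)
  assert_number(q3, "q3", lower = 0, strict_lower = TRUE)
  if (q1 == q3) stopf("degenerate quartiles: q1 == q3 (%g)", q1)
  if (q1 > q3) stopf("q1 (%g) must be < q3 (%g)", q1, q3)
  target <- q3 / q1
  ratio_gap <- function(log_shape) {
    k <- exp(log_shape)
    qs <- stats::qgamma(c(0.25, 0.75), shape = k)
    if (qs[1] <= 0) Inf else qs[2] / qs[1] - target
  }
  # interquartile ratio decreases monotonically from Inf (k -> 0) to 1 (k -> Inf);
  # expand the log-shape bracket until it straddles the target
  lo <- -1; while (is.finite(ratio_gap(lo)) && ratio_gap(lo) <= 0) lo <- lo - 2
  while (!is.finite(ratio_gap(lo))) lo <- lo + 0.5
  hi <- 1; while (ratio_gap(hi) >= 0 && hi < 40) hi <- hi + 2
  root <- stats::uniroot(ratio_gap, lower = lo, upper = hi, tol = 1e-14)
  shape <- exp(root$root)
  scale <- q1 / stats::qgamma(0.25, shape = shape)
  fit <- list(shape = shape, scale = scale)
  got <- stats::qgamma(c(0.25, 0.75), shape = shape, scale = scale)
  if (max(abs(got - c(q1, q3)) / c(q1, q3)) > 1e-6)
    stopf("gamma quartile fit did not converge for (%g, %g)", q1, q3)
  fit
}

#' Convert a transition probability between cycle lengths
#'
#' Assumes a constant underlying event rate: \eqn{p' = 1 - (1-p)^{t'/t}}.
#'
#' @param p Probability over duration `t_from`.
#' @param t_from,t_to Durations (same units), both positive.
#' @return Probability over duration `t_to`.
#' @export
convert_probability <- function(p, t_from, t_to) {
  assert_number(p, "p", lower = 0, upper = 1)
  assert_number(t_from, "t_from", lower = 0, strict_lower = TRUE)
  assert_number(t_to, "t_to", lower = 0, strict_lower = TRUE)
  if (p == 1) {
    if (t_to < t_from) stopf("p = 1 implies an infinite rate; cannot shorten the interval")
    return(1)
  }
  1 - (1 - p)^(t_to / t_from)
}

#' Inflate a monetary amount to 2023 using annual CPI rates
#'
#' Multiplies by \eqn{\prod_y (1 + \mathrm{cpi}_y)} over the years after
#' `year` up to and including 2023. A 2023 amount is returned unchanged.
#'
#' @param amount Amount in RMB of `year`.
#' @param year Calendar year of the amount.
#' @param cpi_table Data frame with columns `year` and `rate`
#'   (proportional annual inflation, e.g. 0.02 for 2%).
#' @return Amount in 2023 RMB.
#' @export
inflate_to_2023 <- function(amount, year, cpi_table) {
  assert_number(amount, "amount")
  assert_number(year, "year")
  if (!is.data.frame(cpi_table) || !all(c("year", "rate") %in% names(cpi_table)))
    stopf("cpi_table must be a data frame with columns `year` and `rate`")
  if (year > 2023) stopf("year %d is after the 2023 reference year", year)
  if (year == 2023) return(amount)
  need <- seq(year + 1, 2023)
  missing <- setdiff(need, cpi_table$year)
  if (length(missing))
    stopf("CPI table missing year(s): %s", paste(missing, collapse = ", "))
  rates <- cpi_table$rate[match(need, cpi_table$year)]
  amount * prod(1 + rates)
}

#' Bundled China CPI table
#'
#' Annual consumer-price inflation rates used to express historical
#' hospitalization costs in 2023 RMB.
#'
#' @return Data frame with columns `year`, `rate`.
#' @export
china_cpi_table <- function() {
  path <- system.file("extdata", "cpi_china.csv", package = "bttcea", mustWork = TRUE)
  utils::read.csv(path)
}
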