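#' @name psm_matching
#' @title Propensity-score estimation, 1:1 matching, balance diagnostics
#'
#' @description
#' Reproduces the cohort-homogenization stage: a logistic propensity model
#' for bridged-vs-non-bridged assignment (fitted by iteratively reweighted
#' least squares through [stats::glm()]), greedy 1:1 nearest-neighbor
#' matching on the logit scale without replacement under a caliper, and
#' standardized-mean-difference / hypothesis-test balance tables before
#' and after matching. Default matching covariates are age group, primary
#' disease, PAWP and mPAP — the covariates that differed before matching.
NULL

#' Default matching covariates
#' @export
default_psm_covariates <- function() c("age_group", "primary_disease", "pawp", "mpap")

#' Fit a logistic propensity-score model
#'
#' Records missing the outcome fields (total cost or any EQ-5D response)
#' are dropped before fitting, mirroring the study's exclusion of
#' participants without complete outcome data.
#'
#' @param records Cohort data frame with an `arm` column.
#' @param covariates Covariate names to enter the linear predictor.
#' @return A `propensity_fit`: `coefficients`, `scores` (named by patient
#'   id, strictly inside (0,1)), `converged`, `n_iterations`,
#'   `separation` flag, `treated` (logical by id), `dropped` (ids removed
#'   for missing outcomes). Complete separation raises a
#'   `bttcea_separation` warning rather than returning silently.
#' @export
fit_propensity <- function(records, covariates = default_psm_covariates()) {
  missing <- setdiff(c("id", "arm", covariates), names(records))
  if (length(missing)) stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  outcome_cols <- intersect(c("total_cost", eq5d_dims), names(records))
  keep <- stats::complete.cases(records[c("arm", covariates, outcome_cols)])
  dropped <- records$id[!keep]
  records <- records[keep, ]
  treated <- records$arm == "tMCS"
  if (sum(treated) < 2L || sum(!treated) < 2L)
    stopf("need at least 2 records per arm")
  for (v in covariates)
    if (length(unique(records[[v]])) < 2L)
      stopf("covariate %s is constant; propensity model not identifiable", v)

  df <- records[covariates]
  df$.treated <- treated
  fit <- suppressWarnings(
    stats::glm(.treated ~ ., data = df, family = stats::binomial()))
  scores <- stats::fitted(fit)
  eps <- 1e-8
  separation <- any(scores > 1 - eps | scores < eps) || !fit$converged
  if (separation)
    warning(structure(class = c("bttcea_separation", "warning", "condition"),
                      list(message = "propensity model shows (near-)complete separation; scores are unreliable",
                           call = NULL)))
  scores <- pmin(pmax(scores, eps), 1 - eps)
  structure(list(coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit),
                 scores = stats::setNames(as.numeric(scores), records$id),
                 treated = stats::setNames(treated, records$id),
                 converged = fit$converged, n_iterations = fit$iter,
                 separation = separation, dropped = as.character(dropped)),
            class = "propensity_fit")
}

#' Greedy 1:1 nearest-neighbor matching with a caliper
#'
#' Treated patients are processed in descending propensity-score order
#' (ties broken by ascending id); each receives the unmatched control
#' with the smallest absolute logit-score gap (ties again by ascending
#' id). Pairs whose gap exceeds the caliper — `caliper_sd_mult` times the
#' SD of the pooled logit scores — are discarded to the unmatched lists.
#' Matching is without replacement and invariant to strictly monotone
#' transformations of the scores only through the logit scale, which is
#' the conventional metric.
#'
#' @param fit A `propensity_fit`.
#' @param caliper_sd_mult Caliper width as a multiple of the logit-score
#'   SD (default 0.2, the conventional choice).
#' @return A `matched_cohort`: `pairs` (data frame `treated_id`,
#'   `control_id`, `gap`), `unmatched_treated`, `unmatched_control`,
#'   `caliper_used` (logit-scale width).
#' @export
nearest_neighbor_match <- function(fit, caliper_sd_mult = 0.2) {
  stopifnot(inherits(fit, "propensity_fit"))
  assert_number(caliper_sd_mult, "caliper_sd_mult", lower = 0)
  lp <- logit(fit$scores)
  t_ids <- names(lp)[fit$treated]
  c_ids <- names(lp)[!fit$treated]
  if (!length(t_ids) || !length(c_ids)) stopf("both arms must be non-empty")
  caliper <- caliper_sd_mult * stats::sd(lp)

  ord <- t_ids[order(-fit$scores[t_ids], t_ids)]
  avail <- c_ids[order(c_ids)]
  pairs <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    if (!length(avail)) break
    gaps <- abs(lp[avail] - lp[ord[k]])
    j <- which.min(gaps)  # first minimum = lowest id among ties
    if (gaps[j] <= caliper) {
      pairs[[k]] <- data.frame(treated_id = ord[k], control_id = avail[j],
                               gap = unname(gaps[j]))
      avail <- avail[-j]
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- data.frame(treated_id = character(), control_id = character(),
                        gap = numeric())
  structure(list(pairs = pairs,
                 unmatched_treated = setdiff(t_ids, pairs$treated_id),
                 unmatched_control = setdiff(c_ids, pairs$control_id),
                 caliper_used = caliper),
            class = "matched_cohort")
}

smd_continuous <- function(x1, x0) {
  s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  if (!is.finite(s) || s == 0) return(if (mean(x1) == mean(x0)) 0 else Inf)
  abs(mean(x1) - mean(x0)) / s
}

smd_binary <- function(p1, p0) {
  s <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  if (s == 0) return(if (p1 == p0) 0 else Inf)
  abs(p1 - p0) / s
}

covariate_balance <- function(x, grp) {
  if (is.numeric(x)) {
    x1 <- x[grp]; x0 <- x[!grp]
    smd <- smd_continuous(x1, x0)
    if (length(unique(x)) < 2L)
      return(list(smd = smd, p = NA_real_, test = "skipped_constant"))
    p <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE)$p.value)
    list(smd = smd, p = p, test = "wilcoxon_rank_sum")
  } else {
    lev <- sort(unique(x))
    if (length(lev) < 2L)
      return(list(smd = 0, p = NA_real_, test = "skipped_constant"))
    if (length(lev) == 2L) {
      p1 <- mean(x[grp] == lev[1]); p0 <- mean(x[!grp] == lev[1])
      smd <- smd_binary(p1, p0)
    } else {
      # multi-level: largest per-level standardized proportion difference
      smd <- max(vapply(lev, function(l)
        smd_binary(mean(x[grp] == l), mean(x[!grp] == l)), numeric(1)))
    }
    tab <- table(factor(x, levels = lev), grp)
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    list(smd = smd, p = p, test = "chi_squared")
  }
}

#' Pre/post-matching balance diagnostics
#'
#' Standardized mean differences — \eqn{|m_1 - m_0| / \sqrt{(s_1^2 +
#' s_0^2)/2}} for continuous covariates, the proportion-difference
#' analogue for binary ones — plus hypothesis tests: Pearson chi-squared
#' for categorical covariates and Wilcoxon rank-sum for the (right-
#' skewed) continuous hemodynamics. Constant covariates get SMD 0 with
#' the test flagged as skipped.
#'
#' @param records Full cohort data frame.
#' @param matched A `matched_cohort`.
#' @param covariates Covariates to diagnose.
#' @return Data frame with per-covariate `smd_pre`, `smd_post`, `p_pre`,
#'   `p_post`, `test`.
#' @export
balance_diagnostics <- function(records, matched,
                                covariates = default_psm_covariates()) {
  stopifnot(inherits(matched, "matched_cohort"))
  if (nrow(matched$pairs) == 0L) stopf("matched cohort is empty")
  missing <- setdiff(covariates, names(records))
  if (length(missing)) stopf("covariate(s) absent from records: %s",
                             paste(missing, collapse = ", "))
  post_ids <- c(matched$pairs$treated_id, matched$pairs$control_id)
  post <- records[match(post_ids, records$id), ]
  rows <- lapply(covariates, function(v) {
    pre <- covariate_balance(records[[v]], records$arm == "tMCS")
    pst <- covariate_balance(post[[v]], post$arm == "tMCS")
    data.frame(covariate = v, smd_pre = pre$smd, smd_post = pst$smd,
               p_pre = pre$p, p_post = pst$p, test = pst$test)
  })
  do.call(rbind, rows)
}
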