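test_that("propensity model rejects non-identifiable inputs", {
  co <- generate_cohort(cohort_config(n = 60, seed = 21))
  co$flat <- 1
  expect_error(fit_propensity(co, "flat"), "constant")
  expect_error(fit_propensity(co[co$arm == "tMCS", ][1:3, ], "pawp"), "per arm")
})

test_that("a covariate independent of the arm gets a near-zero coefficient", {
  set.seed(22)
  n <- 4000
  co <- generate_cohort(cohort_config(n = n, seed = 22))
  co$noise <- rnorm(n)
  fit <- fit_propensity(co, c("age_group", "noise"))
  se <- sqrt(diag(fit$vcov))[["noise"]]
  expect_lt(abs(fit$coefficients[["noise"]]), 3 * se)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # scores are a monotone function of the linear predictor
  X <- cbind(1, co$age_group == "le60", co$noise)  # model.matrix order
  expect_true(all(fit$scores > 0 & fit$scores < 1))
})

test_that("complete separation raises a dedicated diagnostic", {
  co <- generate_cohort(cohort_config(n = 100, seed = 23))
  co$marker <- as.numeric(co$arm == "tMCS")
  expect_warning(fit <- fit_propensity(co, "marker"), class = "bttcea_separation")
  expect_true(fit$separation)
})

test_that("greedy caliper matching reproduces the enumerated pairing", {
  fit <- fake_fit(c(0.6, 0.3), c(0.55, 0.35, 0.9))
  m <- nearest_neighbor_match(fit, caliper_sd_mult = 100)
  expect_equal(m$pairs$treated_id, c("T01", "T02"))
  expect_equal(m$pairs$control_id, c("C01", "C02"))  # 0.6<->0.55, 0.3<->0.35
  expect_equal(m$unmatched_control, "C03")
  expect_equal(m$pairs$gap, abs(qlogis(c(0.6, 0.3)) - qlogis(c(0.55, 0.35))),
               tolerance = 1e-12)
})

test_that("identical score lists pair everyone at zero gap; caliper 0 blocks distinct scores", {
  s <- c(0.2, 0.5, 0.8)
  m <- nearest_neighbor_match(fake_fit(s, s), caliper_sd_mult = 0)
  expect_equal(nrow(m$pairs), 3)
  expect_true(all(m$pairs$gap == 0))
  m2 <- nearest_neighbor_match(fake_fit(c(0.6, 0.3), c(0.55, 0.35, 0.9)), 0)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(sort(m2$unmatched_treated), c("T01", "T02"))
})

test_that("pairs and unmatched lists partition the cohort exactly", {
  co <- generate_cohort(cohort_config(n = 300, seed = 24))
  fit <- fit_propensity(co)
  m <- nearest_neighbor_match(fit)
  ids <- c(m$pairs$treated_id, m$pairs$control_id,
           m$unmatched_treated, m$unmatched_control)
  expect_setequal(ids, co$id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(m$pairs$gap <= m$caliper_used))
})

test_that("matching is invariant to a logit-scale shift of the scores", {
  co <- generate_cohort(cohort_config(n = 300, seed = 25))
  fit <- fit_propensity(co)
  shifted <- fit
  shifted$scores <- plogis(qlogis(fit$scores) + 0.7)  # strictly monotone in p
  m1 <- nearest_neighbor_match(fit)
  m2 <- nearest_neighbor_match(shifted)
  expect_equal(m1$pairs[c("treated_id", "control_id")],
               m2$pairs[c("treated_id", "control_id")])
})

test_that("balance tests match a direct Pearson chi-squared computation", {
  # post-matching sex split: 37/3 male/female bridged vs 30/10 non-bridged
  n <- 40
  recs <- data.frame(
    id = sprintf("P%02d", 1:(2 * n)),
    arm = rep(c("tMCS", "HTx"), each = n),
    sex = c(rep("male", 37), rep("female", 3), rep("male", 30), rep("female", 10)))
  m <- structure(list(pairs = data.frame(treated_id = recs$id[1:n],
                                         control_id = recs$id[(n + 1):(2 * n)],
                                         gap = 0),
                      unmatched_treated = character(),
                      unmatched_control = character(), caliper_used = 1),
                 class = "matched_cohort")
  bal <- balance_diagnostics(recs, m, "sex")
  # brute-force 2x2 Pearson statistic
  tab <- matrix(c(3, 37, 10, 30), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(bal$p_post, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(bal$test, "chi_squared")
})

test_that("identical groups give zero SMDs; constants are flagged as skipped", {
  n <- 30
  base <- data.frame(id = sprintf("A%02d", 1:n), pawp = rlnorm(n, 2.7, 0.3),
                     age_group = rep(c("le60", "gt60"), length.out = n))
  recs <- rbind(transform(base, arm = "tMCS"),
                transform(base, id = sub("A", "B", id), arm = "HTx"))
  m <- structure(list(pairs = data.frame(treated_id = base$id,
                                         control_id = sub("A", "B", base$id),
                                         gap = 0),
                      unmatched_treated = character(),
                      unmatched_control = character(), caliper_used = 1),
                 class = "matched_cohort")
  recs$steady <- 5
  bal <- balance_diagnostics(recs, m, c("pawp", "age_group", "steady"))
  expect_equal(bal$smd_post, c(0, 0, 0))
  expect_equal(bal$test[bal$covariate == "steady"], "skipped_constant")
  expect_error(balance_diagnostics(recs, m, "absent_cov"), "absent")
})

test_that("matching removes the configured confounding on a synthetic cohort", {
  # control-rich cohort so 1:1 matching has adequate overlap
  co <- generate_cohort(cohort_config(n = 2000, arm_fraction = 0.2, seed = 26))
  covs <- default_psm_covariates()
  fit <- fit_propensity(co, covs)
  m <- nearest_neighbor_match(fit)
  bal <- balance_diagnostics(co, m, covs)
  expect_gt(max(bal$smd_pre), 0.1)   # genuine pre-matching imbalance
  expect_true(all(bal$smd_post < 0.1))
})
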