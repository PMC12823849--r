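test_that("the generator returns exactly n validated records, reproducibly", {
  cfg <- cohort_config(n = 80, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(nrow(a), 80)
  expect_identical(a, b)
  expect_true(all(a$arm %in% c("tMCS", "HTx")))
  expect_true(all(a$total_cost >= 0))
  expect_true(all(a[c("ci", "pawp", "pvr", "mpap", "tpg")] > 0))
  for (v in c("mo", "sc", "ua", "pd", "ad"))
    expect_true(all(a[[v]] %in% 1:5))
  expect_false(identical(a, generate_cohort(cohort_config(n = 80, seed = 4))))
})

test_that("configured categorical marginals are recovered at large n", {
  covs <- default_covariate_marginals()
  covs$primary_disease <- list(levels = c("dilated_cardiomyopathy", "other"),
                               probs = c(0.5896, 0.4104))
  cfg <- cohort_config(n = 20000, covariates = covs, seed = 5)
  co <- draw_covariates(cfg)
  expect_lt(abs(mean(co$primary_disease == "dilated_cardiomyopathy") - 0.5896), 0.01)
  # 3-sigma binomial recovery across the arm-independent covariates
  checks <- list(sex = c("male", 0.8507), nyha = c("III", 0.1119),
                 married = c("married", 0.7985), cmv = c("no", 0.8731))
  for (v in names(checks)) {
    p <- as.numeric(checks[[v]][2])
    expect_lt(abs(mean(co[[v]] == checks[[v]][1]) - p),
              3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("arm-conditional confounding shifts are applied where configured", {
  co <- draw_covariates(cohort_config(n = 20000, seed = 6))
  old_t <- mean(co$age_group[co$arm == "tMCS"] == "gt60")
  old_h <- mean(co$age_group[co$arm == "HTx"] == "gt60")
  expect_lt(abs(old_t - 0.3182), 0.015)
  expect_lt(abs(old_h - 0.1618), 0.015)
  dil_t <- mean(co$primary_disease[co$arm == "tMCS"] == "dilated_cardiomyopathy")
  dil_h <- mean(co$primary_disease[co$arm == "HTx"] == "dilated_cardiomyopathy")
  expect_lt(abs(dil_t - 0.6818), 0.015)
  expect_lt(abs(dil_h - 0.5000), 0.015)
  # hemodynamics are drawn from pooled marginals (no arm shift by default)
  expect_lt(abs(median(co$pawp[co$arm == "HTx"]) - median(co$pawp[co$arm == "tMCS"])), 0.5)
})

test_that("continuous hemodynamics match configured medians and IQRs", {
  co <- draw_covariates(cohort_config(n = 20000, seed = 7))
  expect_lt(abs(median(co$ci) - 1.98), 0.05)
  expect_lt(abs(quantile(co$tpg, 0.25) - 7.00), 0.3)
  expect_lt(abs(quantile(co$tpg, 0.75) - 12.00), 0.3)
})

test_that("cost attachment respects the configured arm separation and year", {
  cm <- default_cost_model()
  cm$year <- 2021
  cfg <- cohort_config(n = 20000, cost_model = cm, seed = 8)
  co <- attach_costs(draw_covariates(cfg), cfg)
  expect_true(all(co$cost_year == 2021))
  gap_cfg <- cm$tMCS$mean - cm$HTx$mean
  m_t <- co$total_cost[co$arm == "tMCS"]; m_h <- co$total_cost[co$arm == "HTx"]
  se_gap <- sqrt(var(m_t) / length(m_t) + var(m_h) / length(m_h))
  expect_lt(abs((mean(m_t) - mean(m_h)) - gap_cfg), 3 * se_gap)
})

test_that("EQ-5D attachment follows the configured level probabilities", {
  em <- default_eq5d_model()
  em$tMCS <- rep(list(c(1, 0, 0, 0, 0)), 5)
  em$HTx <- rep(list(c(0, 0, 0, 0, 1)), 5)
  cfg <- cohort_config(n = 500, eq5d_model = em, seed = 9)
  co <- generate_cohort(cfg)
  for (v in c("mo", "sc", "ua", "pd", "ad")) {
    expect_true(all(co[[v]][co$arm == "tMCS"] == 1L))
    expect_true(all(co[[v]][co$arm == "HTx"] == 5L))
  }
  em$tMCS <- rep(list(c(0.7, 0.3, 0, 0, 0)), 5)
  cfg <- cohort_config(n = 20000, arm_fraction = 1, eq5d_model = em, seed = 10)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$mo == 2L) - 0.3), 0.01)
})

test_that("invalid configurations are rejected up front", {
  expect_error(cohort_config(n = 0), "n")
  covs <- default_covariate_marginals()
  covs$sex$probs <- c(0.7, 0.2)
  expect_error(cohort_config(covariates = covs), "sum to 1")
  covs <- default_covariate_marginals()
  covs$shoe_size <- list(levels = c("a", "b"), probs = c(0.5, 0.5))
  expect_error(cohort_config(covariates = covs), "unknown covariate")
  cm <- default_cost_model(); cm$tMCS$cv <- 0
  expect_error(cohort_config(cost_model = cm), "scale")
  em <- default_eq5d_model(); em$HTx[[3]] <- c(0.5, 0.5)
  expect_error(cohort_config(eq5d_model = em), "5 level")
})

test_that("substreams isolate stages: EQ-5D settings never move covariate draws", {
  cfg1 <- cohort_config(n = 200, seed = 12)
  em <- default_eq5d_model()
  em$tMCS <- rep(list(c(0, 0, 0, 0, 1)), 5)
  cfg2 <- cohort_config(n = 200, eq5d_model = em, seed = 12)
  c1 <- generate_cohort(cfg1); c2 <- generate_cohort(cfg2)
  shared <- setdiff(names(c1), c("mo", "sc", "ua", "pd", "ad"))
  expect_identical(c1[shared], c2[shared])
})

test_that("cohorts and configs round-trip through their file formats", {
  cfg <- cohort_config(n = 25, seed = 13)
  co <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(read_cohort(path), co, tolerance = 1e-12)

  ycfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 25", "seed: 13"), ycfg)
  expect_identical(generate_cohort(read_cohort_config(ycfg)), co)
  writeLines(c("n: 25", "banana: true"), ycfg)
  expect_error(read_cohort_config(ycfg), "unknown cohort-config key")
})
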