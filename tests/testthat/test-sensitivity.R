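# a small but fully stochastic base case shared by the DSA/PSA tests
base_specs <- function() {
  list(a = assemble_model("tMCS"), b = assemble_model("HTx"))
}

test_that("the parameter catalog covers every uncertain quantity with fitted SDs", {
  s <- base_specs()
  cat <- psa_parameters(s$a, s$b)
  expect_equal(sum(cat$kind == "transition"), 12)  # 5 bridged + 7 transplant rows
  expect_equal(nrow(cat), 12 + nrow(s$a$costs) + nrow(s$b$costs) +
                 nrow(s$a$utilities) + nrow(s$b$utilities))
  expect_true(all(cat$sd > 0))
  expect_true(all(cat$low <= cat$point & cat$point <= cat$high))
})

test_that("tornado entries match a brute-force re-evaluation on a toy model", {
  # 3 uncertain parameters only: everything else degenerate
  tr_a <- trans_df(list("Survival", "Dead", 0.1, 0.05, 0.15))
  tr_b <- trans_df(list("Survival", "Dead", 0.12, 0.12, 0.12))
  co_a <- cost_df("Survival", 1000, q_spread = c(0.8, 1.3))
  co_b <- cost_df("Survival", 1000, q_spread = c(1, 1))
  ut_a <- util_df("Survival", 0.9)
  ut_b <- util_df("Survival", 0.7, half = 0.05)
  sa <- assemble_model("tMCS", make_params("tMCS", tr_a, co_a, ut_a))
  params_b <- make_params("HTx", rbind(tr_b, trans_df(
    list("Survival", "MCS", 0.0), list("MCS", "Survival", 0.3))),
    co_b, ut_b)
  sb <- assemble_model("HTx", params_b)

  dsa <- one_way_dsa(sa, sb, wtp_ref = 50000, horizon = 10)
  active <- dsa$entries[dsa$entries$range > 0, ]
  expect_equal(nrow(active), 3)

  # independent oracle: rebuild and rerun per bound
  oracle_inmb <- function(mod_a, mod_b) {
    d <- incremental(run_arm(mod_a), run_arm(mod_b), 10)
    50000 * d[["delta_qaly"]] - d[["delta_cost"]]
  }
  sa_lo <- sa; sa_lo$transitions$mean[1] <- 0.05
  sa_hi <- sa; sa_hi$transitions$mean[1] <- 0.15
  e <- active[active$parameter == "tMCS prob Survival->Dead", ]
  expect_equal(e$inmb_low, oracle_inmb(sa_lo, sb), tolerance = 1e-10)
  expect_equal(e$inmb_high, oracle_inmb(sa_hi, sb), tolerance = 1e-10)
  sa_c1 <- sa; sa_c1$costs$mean[1] <- 800
  e <- active[active$parameter == "tMCS cost Survival", ]
  expect_equal(e$inmb_low, oracle_inmb(sa_c1, sb), tolerance = 1e-10)
  # degenerate parameters produce zero range and sort below active ones
  expect_gte(min(dsa$entries$range[1:3]), max(dsa$entries$range[-(1:3)]))
  expect_true(all(dsa$entries$range[-(1:3)] == 0))
})

test_that("INMB responds linearly to a pure cost parameter", {
  s <- base_specs()
  cat <- psa_parameters(s$a, s$b)
  i <- which(cat$parameter == "HTx cost admission")
  ev <- function(value) {
    sb <- s$b; sb$costs$mean[cat$index[i]] <- value
    d <- incremental(run_arm(s$a), run_arm(sb), 10)
    inmb(d[["delta_cost"]], d[["delta_qaly"]], 89358)
  }
  lo <- cat$low[i]; hi <- cat$high[i]; mid <- (lo + hi) / 2
  f_lo <- ev(lo); f_hi <- ev(hi); f_mid <- ev(mid)
  expect_equal(f_mid, (f_lo + f_hi) / 2, tolerance = 1e-9)
  expect_gt(f_hi, f_lo)  # higher comparator cost favors the intervention
})

test_that("bounds that break row mass are skipped with a diagnostic", {
  params <- default_model_params()
  # widen one CI so its high bound pushes Survival outgoing mass over 1
  params$transitions$tMCS$ci_high[2] <- 0.95
  sa <- assemble_model("tMCS", params)
  dsa <- one_way_dsa(sa, assemble_model("HTx"), wtp_ref = 89358)
  expect_true("tMCS prob Survival->Infection" %in% dsa$skipped)
  expect_false("tMCS prob Survival->Infection" %in% dsa$entries$parameter)
})

test_that("degenerate PSA collapses to the deterministic increments", {
  tr <- trans_df(list("Survival", "Dead", 0.1))
  sa <- assemble_model("tMCS", make_params(
    "tMCS", tr, cost_df("Survival", 1000, q_spread = c(1, 1)),
    util_df("Survival", 0.9)))
  sb <- assemble_model("HTx", make_params(
    "HTx", rbind(trans_df(list("Survival", "Dead", 0.12)),
                 trans_df(list("Survival", "MCS", 0), list("MCS", "Survival", 0.3))),
    cost_df("Survival", 900, q_spread = c(1, 1)), util_df("Survival", 0.8)))
  psa <- sample_psa(sa, sb, psa_config(25, seed = 2))
  det <- incremental(run_arm(sa), run_arm(sb), 10)
  expect_true(all(psa$samples$delta_cost == det[["delta_cost"]]))
  expect_true(all(psa$samples$delta_qaly == det[["delta_qaly"]]))
  expect_equal(psa$n_resampled, 0L)
})

test_that("PSA is reproducible by seed and counts iterations correctly", {
  s <- base_specs()
  p1 <- sample_psa(s$a, s$b, psa_config(40, seed = 5))
  p2 <- sample_psa(s$a, s$b, psa_config(40, seed = 5))
  expect_identical(p1$samples, p2$samples)
  expect_equal(nrow(p1$samples), 40)
  p3 <- sample_psa(s$a, s$b, psa_config(40, seed = 6))
  expect_false(identical(p1$samples, p3$samples))
})

test_that("sampled parameters recover their point estimates (small run)", {
  s <- base_specs()
  psa <- sample_psa(s$a, s$b, psa_config(400, seed = 7))
  cat <- psa$parameters
  mc_se <- cat$sd / sqrt(400)
  dev <- abs(colMeans(psa$draws) - cat$point)
  expect_true(all(dev <= 4 * mc_se))
})

test_that("the CEAC equals hand-counted acceptance fractions", {
  ps <- fake_psa_samples(delta_cost = c(-5, -1, 1, 2, 2, 3, 8, 10, 1, 4),
                         delta_qaly = c(1, -1, 1, 2, 0.5, 1, 2, 5, -2, 0),
                         wtp_grid = c(0, 1, 2, 3, 4))
  cv <- ceac(ps)
  hand <- sapply(c(0, 1, 2, 3, 4), function(l)
    mean(l * ps$samples$delta_qaly - ps$samples$delta_cost > 0))
  expect_equal(cv$probability, hand)
  expect_equal(cv$probability[1], mean(ps$samples$delta_cost < 0))
})

test_that("degenerate samples give a step CEAC at the ICER", {
  ps <- fake_psa_samples(rep(200, 8), rep(2, 8), wtp_grid = c(0, 50, 100, 150))
  cv <- ceac(ps)
  expect_equal(cv$probability, c(0, 0, 0, 1))  # jumps above 200/2; ties excluded
})

test_that("the CEAC is non-decreasing when all samples gain QALYs at a cost", {
  set.seed(8)
  ps <- fake_psa_samples(runif(200, 10, 1000), runif(200, 0.1, 2),
                         wtp_grid = seq(0, 2000, 100))
  cv <- ceac(ps)
  expect_true(all(diff(cv$probability) >= 0))
  expect_equal(cv$probability[1], 0)
})

test_that("WTP lookup scans the grid for the first qualifying point", {
  cv <- structure(data.frame(wtp = c(0, 10, 20, 30), probability = c(0, 0.4, 0.6, 0.8)),
                  class = c("ceac_curve", "data.frame"))
  expect_equal(wtp_at_probability(cv, 0)$wtp, 0)
  expect_equal(wtp_at_probability(cv, 0.5)$wtp, 20)
  miss <- wtp_at_probability(cv, 0.9)
  expect_false(miss$reached)
  expect_true(is.na(miss$wtp))
  expect_error(wtp_at_probability(cv, 1.5), "target_prob")
  # scan oracle on a random monotone curve
  set.seed(9)
  p <- cumsum(runif(30)); p <- p / max(p)
  cv2 <- structure(data.frame(wtp = seq(0, 290, 10), probability = p),
                   class = c("ceac_curve", "data.frame"))
  tgt <- 0.37
  expect_equal(wtp_at_probability(cv2, tgt)$wtp,
               cv2$wtp[min(which(p >= tgt))])
})

test_that("CE-plane quadrants follow the increment signs and sum to n", {
  ps <- fake_psa_samples(c(5, -5, 5, -5), c(1, 1, -1, -1))
  pl <- ce_plane(ps)
  expect_equal(as.character(pl$quadrant), c("NE", "SE", "NW", "SW"))
  expect_equal(sum(attr(pl, "quadrant_counts")), 4)
  set.seed(10)
  ps2 <- fake_psa_samples(rnorm(100), rnorm(100))
  expect_equal(sum(attr(ce_plane(ps2), "quadrant_counts")), 100)
  ps3 <- fake_psa_samples(rep(1, 7), rep(1, 7))
  expect_equal(unname(c(attr(ce_plane(ps3), "quadrant_counts"))), c(7, 0, 0, 0))
})

test_that("Monte-Carlo error shrinks as 1/sqrt(n) when n doubles", {
  s <- base_specs()
  ratios <- vapply(1:12, function(rep) {
    p1 <- sample_psa(s$a, s$b, psa_config(80, seed = 100 + rep))
    p2 <- sample_psa(s$a, s$b, psa_config(160, seed = 300 + rep))
    nb1 <- inmb(p1$samples$delta_cost, p1$samples$delta_qaly, 89358)
    nb2 <- inmb(p2$samples$delta_cost, p2$samples$delta_qaly, 89358)
    (sd(nb2) / sqrt(160)) / (sd(nb1) / sqrt(80))
  }, numeric(1))
  expect_gt(mean(ratios), 0.6)
  expect_lt(mean(ratios), 0.85)
})
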