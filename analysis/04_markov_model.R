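#!/usr/bin/env Rscript
# Stage 4 — run the two-arm Markov cohort model.
#
# States: Survival (well after transplant), Infection, RenalFailure,
# MCS re-support (non-bridged arm only), Dead. One-year cycles over a
# 10-year horizon, transitions at cycle midpoints (trapezoidal half-cycle
# correction), 5% annual discount. The default parameter set embeds the
# published transition probabilities; per-state costs and utilities are
# calibrated synthetic fixtures.

suppressPackageStartupMessages(library(bttcea))

specs <- lapply(stats::setNames(nm = c("tMCS", "HTx")), assemble_model)
results <- lapply(specs, run_arm)

for (arm in names(results)) {
  tr <- as.data.frame(unclass(results[[arm]]$trace))
  tr <- cbind(cycle = 0:(nrow(tr) - 1), tr)
  utils::write.csv(tr, sprintf("results/trace_%s.csv", tolower(arm)),
                   row.names = FALSE)
  utils::write.csv(results[[arm]]$horizons,
                   sprintf("results/arm_%s.csv", tolower(arm)),
                   row.names = FALSE)
  surv10 <- 1 - tr$Dead[11]
  cat(sprintf("%s arm: %.1f%% alive at 10 years; discounted 10-y cost %.0f RMB, %.2f QALYs\n",
              arm, 100 * surv10,
              results[[arm]]$horizons$cost[3], results[[arm]]$horizons$qaly[3]))
}
cat("wrote results/trace_*.csv, results/arm_*.csv\n")
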