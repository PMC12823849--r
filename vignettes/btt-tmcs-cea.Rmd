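---
title: "Cost-effectiveness of bridge-to-transplant temporary mechanical circulatory support: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of bridge-to-transplant temporary mechanical circulatory support: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bttcea)
```

## The decision problem

End-stage heart-failure patients awaiting transplantation can be
stabilized with temporary mechanical circulatory support (ECMO, IABP, or
a ventricular assist device) as a bridge to transplantation (BTT-tMCS),
or transplanted directly (non-bridged HTx). Bridging improves
eligibility and post-transplant condition but adds substantial device
and admission costs. `bttcea` implements a payer-perspective
cost-utility comparison of the two strategies for transplant-eligible
Chinese patients: a deterministic two-arm Markov cohort model plus the
cohort-preparation (propensity-score matching), utility-measurement
(EQ-5D-5L), and uncertainty-analysis (tornado, Monte Carlo) machinery
around it.

## The Markov cohort model

Both arms track a closed cohort of transplant recipients over annual
cycles for 10 years. States:

* **Survival** — alive and well after transplantation (both arms start
  here with the full cohort; pre-implantation and waitlist mortality are
  out of model scope).
* **Infection**, **RenalFailure** — post-transplant complications.
  Complications count as survival: a patient who neither recurs nor dies
  returns to Survival the next cycle.
* **MCS** (non-bridged arm only) — post-transplant mechanical
  re-support. A second device is not an option in the bridged arm, so
  its state space excludes MCS and `assemble_model()` rejects a bridged
  parameter set that mentions it.
* **Dead** — absorbing.

A patient makes at most one transition per cycle and cannot hold two
complication states at once. Row composition in
`build_transition_matrix()`:

* Survival: the literature-derived outgoing probabilities (death,
  infection, renal failure, and re-support in the non-bridged arm), with
  the residual mass as a self-loop.
* Complication states: the recurrence probability as a self-loop, the
  arm's background mortality to Dead, and the remainder back to
  Survival. Where complication survivors go is genuinely open; routing
  them to Survival is consistent with complications being survival
  states, and the recurrence/mortality entries are configurable for
  scenario analysis.
* MCS: the return-to-Survival probability, background mortality, and the
  residual mass remains on support.

Rows must sum to 1 within 1e-12; compositions that push a row over unit
mass are errors (or, in sensitivity analyses, skip the offending draw
with a diagnostic).

### Half-cycle correction and discounting

Transitions are taken to occur at cycle midpoints, implemented as
trapezoidal occupancy: cycle $k$ ($k = 0, 1, \dots$) accrues payoffs
against $\tfrac12(\mathrm{occ}_k + \mathrm{occ}_{k+1})$, discounted by
$(1+r)^{-k}$ with $r = 0.05$ per year. One-time admission costs (the
transplant hospitalization, including the device for bridged patients)
are charged undiscounted at cycle 0. Decision-tree packages differ in
whether the first cycle's discount exponent is 0, 1, or ½; the
convention here (exponent $k$, so the first cycle is undiscounted) is
stated explicitly because printed interim-horizon results under other
conventions — in particular first-year QALY totals that exceed the
1 QALY/year ceiling implied by utilities $\le 1$ under trapezoidal
accounting — cannot be reproduced under this one. Interim (1- and
5-year) totals are truncated cumulative sums with the correction applied
to the truncated trace.

## Parameters

### Transition probabilities

The twelve annual transition probabilities (five for the bridged arm,
seven for the non-bridged arm) are literature-derived point estimates
with 95% CIs, shipped as defaults and validated on assembly. They are
taken as given; re-deriving them from their source cohorts is out of
scope. `convert_probability()` supports constant-rate conversion for
non-annual sources.

### Costs and utilities: synthetic, calibrated fixtures

The per-state annual maintenance costs and per-state utilities of the
source setting are not publicly available. The package therefore ships
clearly-labelled synthetic fixtures
(`inst/extdata/model_params_synthetic.yaml`, mirrored by
`default_model_params()`):

* One-time admission costs anchor at the published per-arm
  hospitalization totals (277,799.29 RMB bridged, 193,705.72 RMB
  non-bridged, 2023 RMB).
* Per-state annual costs use fixed severity weights (Survival 1,
  Infection 2.2, RenalFailure 2.8, MCS 3.5) and per-state utilities use
  fixed decrements (0 / 0.06 / 0.10 / 0.15) below an arm-level base; the
  two free scales per arm were solved once, against this engine, so that
  the default 10-year discounted arm totals reproduce the published
  arm-level results (costs 510,361 vs 473,205 RMB; 5.88 vs 4.60 QALYs).
  The calibration is an anchoring device, not an estimate: any
  conclusion that depends on the *distribution* of cost across states
  should be treated as illustrative.
* Cost quartiles are generated from a gamma with coefficient of
  variation 0.25, so the quartile-matched gamma used in sensitivity
  analyses has an analytic mean equal to the point estimate; utility CIs
  use a fixture standard error of 0.015.

Historical amounts are inflated with `inflate_to_2023()` using the
bundled annual CPI table (`china_cpi_table()`).

### Distribution fitting

`beta_from_mean_ci()` maps a 95% CI half-width to a standard deviation
via the normal 0.975 quantile (1.959964) and moment-matches beta shapes;
the fitted mean equals the input mean to machine precision, and
infeasible inputs (implied variance $\ge \mu(1-\mu)$) are explicit
errors. `gamma_from_quartiles()` root-finds the shape whose
interquartile ratio matches $Q_3/Q_1$ (the ratio is strictly decreasing
in the shape, so the bracketed root is unique) and verifies the quartile
round-trip to 1e-6 relative tolerance. Zero-width intervals are treated
as degenerate point masses in sensitivity analyses and as errors in the
fitting functions themselves.

## EQ-5D-5L utilities

Twelve-month health status is coded on the five EQ-5D-5L dimensions
(mobility, self-care, usual activities, pain/discomfort,
anxiety/depression), five levels each, giving the 3,125-state space of
`enumerate_states()`. Profiles map to utility indices through a
pluggable value set (`read_value_set()`, CSV of 3,125 code–value rows)
anchored at 1 for "11111" and 0 for dead, with worse-than-dead values
permitted. Because published national tariff coefficients are external
copyrighted data, the default is `synthetic_value_set()`: an additive
per-dimension decrement construction that is anchored, monotone in every
dimension, and reaches a worse-than-dead minimum — the qualitative shape
of real tariffs, not their coefficients. Analyses intended to be
tariff-faithful must supply the real value set file.

## The synthetic cohort

`generate_cohort()` stands in for the non-public hospital extract. It
emulates: the demographic and hemodynamic marginals of the study
population (categorical covariates from the published demographic table;
log-normal hemodynamics matched to medians and IQRs, chosen because the
measurements are positive and right-skewed); arm-conditional imbalance
in age group and primary disease (the pre-matching confounding the
matching stage must remove); right-skewed gamma hospitalization costs
with arm-specific means; and per-arm EQ-5D level distributions whose
synthetic-tariff means sit near the fixture survival utilities. A single
seed expands into independent substreams for covariates, costs, and
EQ-5D so adding a field never perturbs earlier draws.

It deliberately does **not** emulate: correlation among covariates
beyond arm-conditioning, correlation among EQ-5D dimensions, waitlist
dynamics or donor matching, deaths before transplantation, or any
within-patient cost–utility dependence. Passing tests on this generator
therefore validate the pipeline's statistical machinery, not clinical
conclusions about real cohorts.

## Propensity-score matching

`fit_propensity()` fits a logistic model (IRLS via `stats::glm`) of
bridging on the matching covariates — default age group, primary
disease, PAWP, mPAP — after dropping records with missing outcome data.
Near-complete separation raises a dedicated diagnostic rather than
returning silently. `nearest_neighbor_match()` is greedy 1:1
nearest-neighbor matching on the logit scale without replacement,
processing treated patients in descending score order with deterministic
id-ascending tie-breaks, under a caliper of 0.2 logit-scale standard
deviations (the conventional choice; configurable).
`balance_diagnostics()` reports standardized mean differences
($|m_1-m_0|/\sqrt{(s_1^2+s_0^2)/2}$, with the proportion-variance
analogue for binary covariates), chi-squared tests for categorical
covariates, and rank-sum tests for the skewed hemodynamics.

A structural caveat: with near-equal arm sizes and genuine confounding,
1:1 matching without replacement runs out of close controls in the
high-propensity strata, and residual or even noise-induced imbalance
(through cross-stratum pairs admitted by the caliper) is unavoidable —
at the study-like 134-patient scale the per-covariate SMD noise floor is
itself around 0.2. The package's balance validation therefore uses a
control-rich design (treated fraction 0.2 at n = 2,000, same
confounding), where the matching reliably drives all post-matching SMDs
below 0.1; users matching near-equal arms should expect, and inspect,
residual imbalance.

## Cost-effectiveness outputs

`cea_table()` reports per-horizon (1, 5, 10 years) discounted arm costs
and QALYs, increments, and the ICER $\Delta C/\Delta E$. Dominance is a
labelled classification ("dominant", "dominated", "undefined"), never a
signed ratio, because negative ICERs are ambiguous. Full internal
precision is kept everywhere; monetary rounding to 2 decimals happens
only at serialization (`write_tables()`). Willingness-to-pay thresholds
follow the WHO convention of 1–3 times GDP per capita
(`who_thresholds()`, 2023 default 89,358 RMB). `subgroup_cea()` runs
sex-stratified model pairs and lays out within-arm male–female and
within-sex arm contrasts.

## Sensitivity analyses

**One-way deterministic** (`one_way_dsa()`): each probability and
utility swings over its 95% CI and each cost over its quartiles, one at
a time, with both arms re-run per bound and the incremental net monetary
benefit $\lambda\Delta E - \Delta C$ recomputed at a reference
willingness-to-pay; entries are ranked by INMB range. The reference
$\lambda$ defaults to 1× GDP per capita, a choice this package makes
explicitly because no standard default exists. Bounds that push a
transition row over unit mass are skipped with a diagnostic. Note the
tornado ranking is sensitive to the fixture dispersions (the synthetic
cost quartile spread puts admission costs at the top here).

**Probabilistic** (`sample_psa()`): Monte Carlo over all parameters
jointly — betas for probabilities and utilities, gammas for costs,
sampled independently since no correlation structure is available —
with both arms re-run per iteration at the 10-year horizon (default
1,000 iterations). Draws producing an invalid transition row are
rejected and redrawn, with a count kept. The samples feed the
cost-effectiveness plane (`ce_plane()`) and acceptability curve
(`ceac()`), the latter on a default grid of 0 to 3× GDP in 0.05-GDP
steps (61 points). INMB ties count as *not* cost-effective (strict
inequality), which fixes the CEAC's boundary identities exactly:
CEAC(0) is the fraction of cost-saving draws. `wtp_at_probability()`
returns the smallest grid threshold reaching a target probability, or a
not-reached flag.

## Numerical and testing choices

Probability-vector and trace-conservation tolerances are 1e-12; the
engine is verified against an independently coded per-cycle accumulation
to 1e-10 relative error and against the closed-form trapezoidal annuity
$\sum_k \tfrac12(s^k+s^{k+1})c(1+r)^{-k}$ for one-state models. Test
problem sizes were chosen to make sampling noise negligible relative to
the tolerance being checked: marginal-recovery checks use cohorts of
20,000 with 3-sigma binomial bands, parameter-recovery uses 5,000 PSA
iterations against 3 Monte-Carlo SEs, and the matching validation uses
40 seeds at n = 2,000. All randomness flows from explicit seeds; equal
seeds reproduce byte-identical cohorts, matches, and PSA samples.

## Known limitations

* Per-state costs and utilities are calibrated fixtures, not estimates;
  only arm-level 10-year totals are anchored.
* The default tariff is synthetic; national value-set coefficients must
  be supplied for tariff-faithful utilities.
* Transitions are time-homogeneous (no tunnel states), the cohort is
  deterministic (no microsimulation), and parameters are sampled
  independently in the PSA.
* 1:1 matching near equal arm sizes leaves residual imbalance by
  construction; the matched count is therefore not a reproduction
  target.
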