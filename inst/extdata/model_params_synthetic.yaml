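transitions:
  tMCS:
  - from: Survival
    to: Dead
    mean: 0.046
    ci_low: 0.039
    ci_high: 0.053
  - from: Survival
    to: Infection
    mean: 0.366
    ci_low: 0.312
    ci_high: 0.419
  - from: Infection
    to: Infection
    mean: 0.362
    ci_low: 0.333
    ci_high: 0.392
  - from: Survival
    to: RenalFailure
    mean: 0.426
    ci_low: 0.41
    ci_high: 0.442
  - from: RenalFailure
    to: RenalFailure
    mean: 0.074
    ci_low: 0.07
    ci_high: 0.078
  HTx:
  - from: Survival
    to: Dead
    mean: 0.05
    ci_low: 0.043
    ci_high: 0.057
  - from: Survival
    to: Infection
    mean: 0.269
    ci_low: 0.22
    ci_high: 0.318
  - from: Infection
    to: Infection
    mean: 0.362
    ci_low: 0.333
    ci_high: 0.392
  - from: Survival
    to: RenalFailure
    mean: 0.302
    ci_low: 0.287
    ci_high: 0.317
  - from: RenalFailure
    to: RenalFailure
    mean: 0.074
    ci_low: 0.07
    ci_high: 0.078
  - from: Survival
    to: MCS
    mean: 0.037
    ci_low: 0.027
    ci_high: 0.047
  - from: MCS
    to: Survival
    mean: 0.33
    ci_low: 0.306
    ci_high: 0.354
costs:
  tMCS:
  - label: admission
    type: one_time
    state: Survival
    mean: 277799.29
    q1: 228351.94
    q3: 320970.88
    source_year: 2023.0
  - label: Survival
    type: per_cycle
    state: Survival
    mean: 20123.4
    q1: 16541.5
    q3: 23250.69
    source_year: 2023.0
  - label: Infection
    type: per_cycle
    state: Infection
    mean: 44271.48
    q1: 36391.3
    q3: 51151.52
    source_year: 2023.0
  - label: RenalFailure
    type: per_cycle
    state: RenalFailure
    mean: 56345.52
    q1: 46316.21
    q3: 65101.93
    source_year: 2023.0
  HTx:
  - label: admission
    type: one_time
    state: Survival
    mean: 193705.72
    q1: 159226.75
    q3: 223808.69
    source_year: 2023.0
  - label: Survival
    type: per_cycle
    state: Survival
    mean: 25173.15
    q1: 20692.41
    q3: 29085.2
    source_year: 2023.0
  - label: Infection
    type: per_cycle
    state: Infection
    mean: 55380.93
    q1: 45523.31
    q3: 63987.44
    source_year: 2023.0
  - label: RenalFailure
    type: per_cycle
    state: RenalFailure
    mean: 70484.82
    q1: 57938.76
    q3: 81438.56
    source_year: 2023.0
  - label: MCS
    type: per_cycle
    state: MCS
    mean: 88106.03
    q1: 72423.45
    q3: 101798.21
    source_year: 2023.0
utilities:
  tMCS:
  - state: Survival
    mean: 0.9324
    ci_low: 0.903
    ci_high: 0.9618
  - state: Infection
    mean: 0.8724
    ci_low: 0.843
    ci_high: 0.9018
  - state: RenalFailure
    mean: 0.8324
    ci_low: 0.803
    ci_high: 0.8618
  HTx:
  - state: Survival
    mean: 0.7492
    ci_low: 0.7198
    ci_high: 0.7786
  - state: Infection
    mean: 0.6892
    ci_low: 0.6598
    ci_high: 0.7186
  - state: RenalFailure
    mean: 0.6492
    ci_low: 0.6198
    ci_high: 0.6786
  - state: MCS
    mean: 0.5992
    ci_low: 0.5698
    ci_high: 0.6286
settings:
  cycle_length: 1.0
  horizon: 10.0
  discount_rate: 0.05
  report_horizons:
  - 1.0
  - 5.0
  - 10.0
  gdp_per_capita: 89358.0
  currency_year: 2023.0
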