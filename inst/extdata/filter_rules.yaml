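# Default candidate-deselection rule pipeline.
#
# The rule classes mirror the stepwise KPI deselection used in equation
# development: poor MAE / P30, unstable cross-validation MAE, inability to
# reach the upper GFR range, heteroscedastic residuals, and redundancy
# among closely related formulas. Thresholds here are illustrative
# defaults; the original stepwise thresholds were chosen by subject-matter
# experts on their own data and are expected to be tuned per cohort.
rules:
  - id: mae_cap
    type: threshold
    field: train_mae
    op: "<="
    threshold: 15
  - id: p30_floor
    type: threshold
    field: train_p30
    op: ">="
    threshold: 75
  - id: cv_stability
    type: threshold
    field: cv_mae_cv
    op: "<="
    threshold: 0.25
  - id: upper_range_reach
    type: threshold
    field: upper_range_reach
    op: ">="
    threshold: 0.5
  - id: heteroscedasticity
    type: threshold
    field: heteroscedasticity
    op: "<="
    threshold: 0.3
  - id: redundancy
    type: redundancy
    min_shared: 3
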