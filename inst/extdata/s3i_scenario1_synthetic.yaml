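# Scenario 1 parameter set: SAPIEN 3 (PARTNER S3i propensity-matched
# comparison) one-year clinical outcomes, extrapolated to five years
# assuming the early mortality benefit persists (linear increase in
# cumulative mortality from the last observed readout).
#
# SYNTHETIC RECONSTRUCTION. The full milestone table for this scenario is
# not published in an accessible form. The TAVI column is rebuilt from the
# published PARTNER S3i one-year outcomes and the anchor values 6.5%
# (1-year) / 26.8% (extrapolated 5-year) TAVI and 12.3% / 41.3% SAVR
# all-cause mortality; TAVI adverse-event milestones beyond one year are
# extended with the base-case TAVI conditional interval rates. The SAVR
# column reuses the PARTNER 2A SAVR base-case values (the S3i comparison
# used the PARTNER 2A surgical arm). Treat scenario-1 outputs as a
# reconstruction, not a verbatim reproduction.
name: s3i_scenario1
description: >-
  Scenario 1 (synthetic reconstruction): PARTNER S3i one-year outcomes
  extrapolated to five years; all other inputs as in the base case.
settings:
  horizon_months: 60
  cycle_length_months: 1
  annual_discount: 0.03
  wtp: 34091
  n_microsim: 10000
  n_psa: 5000
  seed: 1
  apply_ae_disutilities: no
  mortality_bridge: linear
  mortality_linear_from: 12
  half_cycle_correction: no
milestone_months: [1, 12, 24, 60]
events:
  all_cause_mortality:
    kind: cumulative_incidence
    tavi: [0.011, 0.065, 0.116, 0.268]
    savr: [0.041, 0.123, 0.196, 0.413]
  disabling_stroke:
    kind: cumulative_incidence
    tavi: [0.009, 0.023, 0.033, 0.068]
    savr: [0.042, 0.060, 0.067, 0.083]
  rehospitalisation:
    kind: cumulative_incidence
    tavi: [0.046, 0.114, 0.168, 0.307]
    savr: [0.065, 0.148, 0.171, 0.241]
  MI:
    kind: cumulative_incidence
    tavi: [0.003, 0.018, 0.029, 0.093]
    savr: [0.018, 0.032, 0.042, 0.081]
  major_vascular:
    kind: cumulative_incidence
    tavi: [0.061, 0.063, 0.065, 0.071]
    savr: [0.039, 0.043, 0.045, 0.051]
  bleeding:
    kind: cumulative_incidence
    tavi: [0.046, 0.054, 0.081, 0.160]
    savr: [0.414, 0.434, 0.447, 0.486]
  endocarditis:
    kind: cumulative_incidence
    tavi: [0.000, 0.007, 0.014, 0.036]
    savr: [0.000, 0.009, 0.009, 0.019]
  AKI:
    kind: cumulative_incidence
    tavi: [0.010, 0.015, 0.018, 0.027]
    savr: [0.030, 0.052, 0.064, 0.100]
  new_PPI:
    kind: cumulative_incidence
    tavi: [0.102, 0.124, 0.141, 0.177]
    savr: [0.071, 0.095, 0.108, 0.135]
  TIA:
    kind: cumulative_incidence
    tavi: [0.009, 0.020, 0.031, 0.050]
    savr: [0.003, 0.018, 0.023, 0.043]
  AF:
    kind: cumulative_incidence
    tavi: [0.050, 0.060, 0.075, 0.118]
    savr: [0.267, 0.276, 0.278, 0.307]
  PAR:
    kind: prevalence
    tavi: [0.015, 0.015, 0.020, 0.015]
    savr: [0.0049, 0.0049, 0.0057, 0.0034]
hazard_ratios:
  by_cycle: [8.5, 4.72, 3.58, 2.97, 2.63, 2.21, 2.15, 1.83, 1.86,
             1.5, 1.51, 1.42, 1.22, 1.19, 1.16]
  after: 1.0
costs:
  index_episode:
    tavi: 54301
    savr: 26109
  followup_annual: 372
  neurologist_visit: 243
  ae:
    disabling_stroke:  {mean: 14243, sd: 11914, ci_low: 4252, ci_high: 47508}
    rehospitalisation: {mean: 6120,  sd: 9280,  ci_low: 667,  ci_high: 26476}
    MI:                {mean: 13736, sd: 13143, ci_low: 1436, ci_high: 44309}
    major_vascular:    {mean: 13773, sd: 13858, ci_low: 3486, ci_high: 54403}
    bleeding:          {mean: 8652,  sd: 7524,  ci_low: 2408, ci_high: 30786}
    endocarditis:      {mean: 26952, sd: 29945, ci_low: 1813, ci_high: 114305}
    AKI:               {mean: 6203,  sd: 8445,  ci_low: 711,  ci_high: 28414}
    new_PPI:           {mean: 13384, sd: 8805,  ci_low: 5856, ci_high: 34942}
    TIA:               {mean: 2842,  sd: 2213,  ci_low: 749,  ci_high: 7819}
    AF:                {mean: 5152,  sd: 8535,  ci_low: 597,  ci_high: 25330}
    PAR:               {mean: 22231, sd: 20436, ci_low: 831,  ci_high: 69572}
utilities:
  tavi:
    - {month: 1,  mean: 0.81, ci_low: 0.79, ci_high: 0.82}
    - {month: 12, mean: 0.79, ci_low: 0.78, ci_high: 0.81}
    - {month: 24, mean: 0.78, ci_low: 0.76, ci_high: 0.79}
  savr:
    - {month: 1,  mean: 0.73, ci_low: 0.71, ci_high: 0.74}
    - {month: 12, mean: 0.80, ci_low: 0.78, ci_high: 0.81}
    - {month: 24, mean: 0.77, ci_low: 0.75, ci_high: 0.79}
  pooled_after_month: 24
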