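# Scenario 2 parameter set: CoreValve self-expanding system (SURTAVI
# randomised trial) two-year clinical outcomes; beyond 24 months both arms
# follow the SAVR-arm second-year risk projected linearly, so the
# between-arm mortality gap is frozen after the last observed readout.
#
# SYNTHETIC RECONSTRUCTION. The scenario's milestone table is not published
# in an accessible form; values are rebuilt from the published SURTAVI
# 30-day/1-year/2-year outcomes (near-equal all-cause mortality at two
# years, markedly higher pacemaker implantation and paravalvular
# regurgitation with the self-expanding valve, higher bleeding/atrial
# fibrillation/kidney injury with surgery) with the five-year values
# obtained by adding the SAVR second-year cumulative increment linearly to
# both arms. PARTNER 2A utilities and Singapore costs are retained. Treat
# scenario-2 outputs as a reconstruction, not a verbatim reproduction.
name: surtavi_scenario2
description: >-
  Scenario 2 (synthetic reconstruction): SURTAVI two-year outcomes with
  SAVR-rate linear projection beyond 24 months; other inputs as base case.
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
  mortality_linear_from: 24
  half_cycle_correction: no
milestone_months: [1, 12, 24, 60]
events:
  all_cause_mortality:
    kind: cumulative_incidence
    tavi: [0.022, 0.067, 0.114, 0.258]
    savr: [0.017, 0.068, 0.116, 0.260]
  disabling_stroke:
    kind: cumulative_incidence
    tavi: [0.012, 0.021, 0.026, 0.047]
    savr: [0.025, 0.038, 0.045, 0.066]
  rehospitalisation:
    kind: cumulative_incidence
    tavi: [0.035, 0.100, 0.140, 0.245]
    savr: [0.040, 0.095, 0.130, 0.235]
  MI:
    kind: cumulative_incidence
    tavi: [0.004, 0.015, 0.020, 0.053]
    savr: [0.006, 0.014, 0.025, 0.058]
  major_vascular:
    kind: cumulative_incidence
    tavi: [0.060, 0.062, 0.064, 0.067]
    savr: [0.011, 0.012, 0.013, 0.016]
  bleeding:
    kind: cumulative_incidence
    tavi: [0.122, 0.136, 0.145, 0.196]
    savr: [0.093, 0.130, 0.147, 0.198]
  endocarditis:
    kind: cumulative_incidence
    tavi: [0.000, 0.006, 0.009, 0.027]
    savr: [0.000, 0.007, 0.013, 0.031]
  AKI:
    kind: cumulative_incidence
    tavi: [0.017, 0.020, 0.022, 0.028]
    savr: [0.044, 0.048, 0.050, 0.056]
  new_PPI:
    kind: cumulative_incidence
    tavi: [0.259, 0.285, 0.300, 0.318]
    savr: [0.066, 0.080, 0.086, 0.104]
  TIA:
    kind: cumulative_incidence
    tavi: [0.011, 0.022, 0.031, 0.046]
    savr: [0.007, 0.015, 0.020, 0.035]
  AF:
    kind: cumulative_incidence
    tavi: [0.129, 0.141, 0.148, 0.166]
    savr: [0.434, 0.450, 0.456, 0.474]
  PAR:
    kind: prevalence
    tavi: [0.053, 0.053, 0.053, 0.053]
    savr: [0.006, 0.006, 0.006, 0.006]
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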