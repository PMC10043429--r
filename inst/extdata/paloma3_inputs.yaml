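# Base-case model inputs: two-arm Markov cohort model of palbociclib plus
# fulvestrant vs placebo plus fulvestrant, Chinese healthcare system
# perspective, all costs in USD. Bounds and distribution tags feed the
# one-way DSA and the PSA.
model:
  cycle_length_days: 28
  horizon_years: 10
  discount_rate: {base: 0.05, lower: 0.0, upper: 0.08, distribution: normal}
  # natural mortality of the 2021 Chinese population, applied directly as
  # the per-cycle PFS->Death transition probability
  background_mortality: {value: 0.00718, timescale: cycle}
arms:
  palbociclib:
    label: Palbociclib plus fulvestrant
    includes_palbociclib: yes
    pfs: {family: weibull, shape: 0.95501, scale: 0.06497}
    os: {family: weibull, shape: 1.30497, scale: 0.00656}
  placebo:
    label: Placebo plus fulvestrant
    includes_palbociclib: no
    pfs: {family: weibull, shape: 0.8904, scale: 0.1405}
    os: {family: weibull, shape: 1.34619, scale: 0.00727}
costs:
  palbociclib_per_cycle: {base: 640.39, lower: 525.12, upper: 768.49, distribution: gamma}
  fulvestrant_per_250mg: {base: 287.90, lower: 233.77, upper: 338.71, distribution: gamma}
  followup_per_cycle: {base: 166.0, lower: 132.8, upper: 193.02, distribution: gamma}
  administration_per_cycle: {base: 33.56, lower: 28.27, upper: 40.27, distribution: gamma}
  supportive_care_per_cycle: {base: 807.0, lower: 690.39, upper: 953.34, distribution: gamma}
  terminal_care_once: {base: 1893.0, lower: 1533.33, upper: 2209.13, distribution: gamma}
ae_costs:
  neutropenia: {base: 412.0, lower: 333.72, upper: 468.18, distribution: gamma}
  leukopenia: {base: 435.58, lower: 378.95, upper: 537.75, distribution: gamma}
  infections: {base: 395.82, lower: 351.49, upper: 494.77, distribution: gamma}
  fatigue: {base: 110.0, lower: 89.50, upper: 129.41, distribution: gamma}
  nausea: {base: 323.0, lower: 261.63, upper: 375.58, distribution: gamma}
ae_incidence:
  palbociclib:
    neutropenia: {base: 0.577, lower: 0.467, upper: 0.704, distribution: beta}
    leukopenia: {base: 0.377, lower: 0.318, upper: 0.459, distribution: beta}
    infections: {base: 0.046, lower: 0.041, upper: 0.055, distribution: beta}
    fatigue: {base: 0.029, lower: 0.024, upper: 0.034, distribution: beta}
    nausea: {base: 0.006, lower: 0.005, upper: 0.007, distribution: beta}
  placebo:
    leukopenia: {base: 0.006, lower: 0.005, upper: 0.007, distribution: beta}
    infections: {base: 0.035, lower: 0.028, upper: 0.043, distribution: beta}
    fatigue: {base: 0.012, lower: 0.01, upper: 0.015, distribution: beta}
    nausea: {base: 0.006, lower: 0.005, upper: 0.007, distribution: beta}
utilities:
  pfs: {base: 0.87, lower: 0.72, upper: 0.96, distribution: beta}
  pd: {base: 0.71, lower: 0.58, upper: 0.82, distribution: beta}
accrual:
  followup: alive
  supportive_care: pfs
  ae_mode: per_cycle
schedule:
  fulvestrant_mg_per_admin: 500
  fulvestrant_vial_mg: 250
  fulvestrant_admins_cycle1: 2
  fulvestrant_admins_later: 1
wtp_thresholds: [34138.28]
psa:
  n_draws: 1000
  seed: 20230314
currency:
  code: USD
  rmb_per_usd: 7.116
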