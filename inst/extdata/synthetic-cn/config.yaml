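country: CN
discount: 0.03
wtp:
  lower: 89300.0
  upper: 267900.0
ppp_usd: 0.239234449760766
risk_model: synthetic
adherence:
  name: base
  intensive: 0.7
  standard: 0.75
profile:
  male: 0.465
  diabetes: 0.19
  smoking: 0.2
  sbp:
    intensive: 127.0
    standard: 136.0
settings:
  start_age: 66.0
  trial_years: 4.0
  cohort_size: 10000.0
  repeat_cvd_multiplier: 1.0
  ae_post_multiplier: 1.0
  cv_risk_multiplier: 1.0
  half_cycle: no
  py_timing: mid
  cost_cv: 0.2
  utility_cv: 0.1
files:
  rates: rates.csv
  life_table: life_table.csv
  costs: costs.csv
  utilities: utilities.csv
  risk_coefficients: risk_coefficients.csv
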