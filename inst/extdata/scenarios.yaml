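# Scenario battery: twelve scenarios per country (3 x 12 = 36 runs).
# Each entry is a scenario_spec(); unspecified fields inherit the base case.
- name: base
- name: discount_0
  discount: 0.0
- name: discount_5
  discount: 0.05
- name: worst_adherence
  adherence: worst
- name: best_adherence
  adherence: best
- name: repeat_cvd_x1.5
  repeat_cvd_multiplier: 1.5
- name: repeat_cvd_x2
  repeat_cvd_multiplier: 2.0
- name: sprint_hr_0.68
  treatment_effect_hr: 0.68
- name: horizon_10y
  horizon: 10
- name: horizon_20y
  horizon: 20
- name: intervention_cost_x1.2
  cost_multipliers:
    intervention: 1.2
- name: cvd_risk_x1.25
  cv_risk_multiplier: 1.25
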