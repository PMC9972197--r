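# htncea

Lifetime cost-effectiveness of **intensive (110–130 mm Hg) vs standard
(130–150 mm Hg) systolic blood pressure control** in hypertensive
adults aged 66+, as a deterministic Markov cohort model with the full
health-economics toolchain: discounted costs and QALYs, ICER and net
monetary benefit, tornado and probabilistic sensitivity analysis,
scenario/subgroup batteries, and trial-period validation — for the
health systems of China, the US and the UK.

Intensive control prevents cardiovascular events but costs more and
causes more treatment-related adverse events. The package quantifies
that trade-off for people who build or review decision models: health
economists, HTA analysts and methods-minded clinicians.

## The model in brief

A cohort enters at age 66 event-free and moves through seven states in
one-year cycles — `no_cvd`, four chronic post-event states
(`chronic_chd`, `post_stroke`, `chronic_hf`, `chronic_af`) and death
split by cause (`dead_cv`, `dead_noncv`). Within a cycle: death first,
then at most one cardiovascular event among survivors (stroke, ACS,
acute heart failure, revascularization, AF, CV death as a competing
multinomial), then state-preserving adverse events.

- Cycles 1–4 use the yearly transition probabilities observed in the
  4-year randomized trial of the two targets (`step_event_rates()`).
- Later cycles extrapolate with a proportional-hazards risk equation,
  `risk = 1 − S0^exp(Σ βj (xj − x̄j))`, evaluated at the cohort's age
  and each arm's achieved SBP, split across event types by the arm's
  trial case mix; non-CVD death comes from a national life table net of
  modeled CV death. All mixing is done in rate space via
  `r = −ln(1 − p)` and `p = 1 − e^(−rt)`.
- After the trial only a fraction of each arm holds its target
  (70%/75% base, 0%/100% worst, 100%/75% best); the non-adherent
  intensive fraction reverts to standard rates and costs.
- Outputs: `ICER = ΔC/ΔE`, `NMB(λ) = λΔE − ΔC` at each country's two
  willingness-to-pay thresholds, and CV events averted per 1000
  patients. Discounting at 3.0% (CN, US) / 3.5% (UK).

Costs, utilities, life tables and risk-equation coefficients are
user-supplied data files; the package ships a seeded **synthetic**
generator for all of them so every stage runs out of the box (see the
vignette for what the synthetic inputs do and do not represent).

## Worked example

```r
library(htncea)

inputs <- generate_inputs(synthetic_profile("CN", seed = 1))
fit <- run_cea(inputs)            # lifetime, both arms
fit
#> Markov cohort CE model: intensive vs standard BP control, CN, horizon lifetime
#> <ce_result> CN, intensive vs standard BP control
#>   QALYs: 11.067 vs 11.000  (delta +0.0674)
#>   Costs: CNY121285 vs CNY117772  (delta +3512)
#>   ICER: CNY52,129 per QALY gained
#>   NMB at WTP CNY89,300 / CNY267,900: +2505 / +14539
#>   CV events averted: 178 per 1000 patients
```

Intensive control gains 0.067 discounted QALYs per patient for an extra
¥3,512 — ¥52,129 per QALY gained, well under the lower willingness-to-pay
threshold (1× GDP per capita, ¥89,300), and 178 cardiovascular events
averted per 1000 patients. On these *synthetic* costs and utilities the
direction and order of magnitude — not the exact figures — are the
point.

Trial-period validation compares the model's 4-year primary-outcome
incidence with the trial's:

```r
validate_trial_period(inputs)
#> <validation_report> 4-year trial window
#>   intensive model 0.990 vs observed 1.00 per 100 py (diff -0.010)
#>   standard  model 1.493 vs observed 1.40 per 100 py (diff +0.093)
#>   PASS (tolerance 0.15 per 100 py)
```

Uncertainty analysis:

```r
simulate(fit, nsim = 1000, seed = 1)   # PSA: CEAC, CE plane, quadrants
one_way_tornado(inputs)                # ±10% tornado, ranked ICER intervals
run_scenario_battery()                 # 3 countries x 12 scenarios
run_subgroup_battery(inputs)           # age/sex/SBP/diabetes/measurement
```

A command-line wrapper with the same functionality (subcommands
`run-base`, `run-psa`, `tornado`, `scenarios`, `subgroups`, `validate`,
`synth`) is installed at `inst/cli/htncea`.

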