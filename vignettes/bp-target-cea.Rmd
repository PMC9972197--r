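---
title: "Modelling the lifetime cost-effectiveness of intensive blood pressure targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifetime cost-effectiveness of intensive blood pressure targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncea)
```

## The question and the model

Intensive systolic blood pressure control (a 110–130 mm Hg target) in
hypertensive adults aged 66 and over prevents cardiovascular events
relative to a standard 130–150 mm Hg target, but costs more — extra
antihypertensive medication, clinic visits and laboratory monitoring —
and causes more treatment-related adverse events (hypotension,
dizziness, syncope, fracture, acute kidney injury). `htncea` weighs
these against each other over a lifetime with a discrete-time Markov
cohort model and reports the trade-off as an incremental
cost-effectiveness ratio (ICER), from the health-care payer's
perspective, for China, the US and the UK.

The cohort starts at age 66, entirely event-free, and moves through
seven states in one-year cycles: `no_cvd`, four chronic post-event
states (`chronic_chd`, `post_stroke`, `chronic_hf`, `chronic_af`) and
death, which we split into `dead_cv` and `dead_noncv` so cardiovascular
deaths can be counted as events while life-table mortality acts as a
competing risk. Clinically this is the usual six-state hypertension
structure; the split is bookkeeping, and reported "death" is the union.

Within a cycle, events resolve in a fixed order, each drawn from the
mass that survived the previous stage:

1. **death** — cardiovascular death (an event of the trial's primary
   composite), then non-cardiovascular death on the remainder;
2. **one cardiovascular event** among survivors — stroke, acute
   coronary syndrome (ACS), acute heart failure, coronary
   revascularization or atrial fibrillation (AF), treated as a competing
   multinomial built from the marginal yearly probabilities with the
   residual meaning "no event". Stroke sends the fraction to
   `post_stroke`, ACS and revascularization to `chronic_chd`, acute
   heart failure to `chronic_hf`, AF to `chronic_af`;
3. **adverse events**, which keep the cohort in place and only accrue
   costs and utility decrements.

Making events conditional on surviving the cycle is the common
convention; with yearly probabilities around 1% the approximation error
of "at most one cardiovascular event per cycle" is second-order.
Resolving non-cardiovascular death on the mass that survived
cardiovascular death (rather than on the full mass) is what lets a
terminal-age death probability of 1 extinguish the cohort cleanly.

## Probabilities: trial phase and extrapolation

All probability arithmetic runs through the constant-hazard transforms
$r = -\ln(1-p)/t$ and $p = 1 - e^{-rt}$ (`prob_to_rate()`,
`rate_to_prob()`). Blending arms, subtracting competing mortality and
rescaling durations all happen in rate space and are then
back-transformed.

**Cycles 1–4 (trial phase).** The per-arm yearly probabilities of the
thirteen tracked event types come verbatim from the 4-year randomized
trial of the two targets in patients aged 60–80
(`step_event_rates()`). Non-cardiovascular death is the rate-space
residual of all-cause minus cardiovascular death.

**Cycles 5+ (extrapolation).** Trial rates cannot be carried to ages
where they were never observed, so cardiovascular risk switches to a
proportional-hazards risk equation of the SCORE2/SCORE2-OP form,

$$\text{risk}_{10}(x) = 1 - S_0^{\exp\left(\sum_j \beta_j (x_j - \bar
x_j)\right)} \times \text{scale},$$

evaluated each year at the cohort's current age and each arm's achieved
systolic pressure (127 vs 136 mm Hg by default). The 10-year composite
risk is annualized and split across the six cardiovascular event types
in proportion to the arm's own trial-period case mix (in rate space, so
the per-event rates sum exactly to the composite rate). Published
coefficient sets can be supplied as data files
(`load_risk_coefficients()`); the package ships a synthetic default
(below) because the published equations' full recalibrations are
supplementary material we deliberately treat as user-supplied input.
Non-cardiovascular death comes from the country life table net of the
modeled cardiovascular death rate, floored at zero.

**Adherence.** After the trial, only a fraction of each arm is assumed
to hold its target: 70%/75% (intensive/standard) in the base case,
0%/100% in the worst case, 100%/75% in the best case. The non-adherent
intensive fraction reverts to standard-target event rates and
standard-intensity treatment cost, so the intensive arm's post-trial
rates are the rate-space blend
$1-\exp\{-(a\,r_{\text{int}}+(1-a)\,r_{\text{std}})\}$. No worse-off
alternative is defined for standard non-adherers, so the standard arm's
adherence value is inert — which is why only the intensive fraction
varies across the three named scenarios.

## Accrual, discounting and summary measures

Each cycle accrues, on the start-of-cycle occupancy:

- **costs** — background health care plus the arm's yearly intervention
  cost for everyone alive, chronic-state costs for the post-event
  states, and one-time acute costs per incident event;
- **QALYs** — the age-adjusted state utility
  $\max(0,\ u_0 - \delta_{\text{age}}(a - 66) - \delta_s)$, minus
  per-event decrements weighted by duration (acute kidney injury 4
  weeks, fracture 12 weeks, other adverse events 2 weeks, acute
  cardiovascular events configurable; all well under one cycle, so the
  decrement lands only in the event cycle). The age decrement is applied
  additively; whether the source model did so additively or
  multiplicatively is not stated, and the choice is isolated in
  `accrue_cycle()`.

Both streams are discounted by $(1+d)^{-(k-1)}$ with one rate per
country (3.0% China/US, 3.5% UK), so year one is undiscounted and a
constant-mortality cohort reproduces the geometric series
$u(1+d)/(d+p)$ exactly — one of the closed forms the tests pin down.
There is no half-cycle correction by default, matching the
spreadsheet/decision-tree lineage of this model family; a
`half_cycle` setting averages start- and end-of-cycle occupancy for
state accrual if wanted. Chronic-state costs and utilities begin the
cycle after the event, automatically, because transitions land at the
next cycle start.

`compute_ce()` forms $\Delta C$, $\Delta E$ (intensive minus standard),
the ICER $\Delta C/\Delta E$ (undefined and flagged when
$\Delta E = 0$; dominance flagged when the signs make a ratio
misleading), net monetary benefit $\lambda\Delta E - \Delta C$ at the
country's two willingness-to-pay thresholds, and cardiovascular events
averted per 1000 patients. ICERs are reported rounded half away from
zero to whole currency units.

## Uncertainty analysis

**One-way (tornado).** Every scalar parameter — each yearly
probability, cost and utility — is moved to ±10% of its base value
(probabilities and utilities capped at 1) with everything else fixed,
and the model is re-run; parameters are ranked by the width of the
resulting ICER interval. On the packaged synthetic inputs the yearly
intervention cost and the stroke/ACS risks dominate, the same
qualitative ranking the published tornado shows.

**Probabilistic (PSA).** 1000 Monte Carlo parameter draws, independent
across parameters: Beta distributions moment-matched to the trial
table's (mean, SD) for probabilities (log-normal where the table says
so), Gamma for costs and Beta for utilities — the standard
cost-effectiveness conventions, since the source specifies
distributions only for the probability rows. Costs default to a 20%
coefficient of variation and utilities to 10% (`cost_cv`,
`utility_cv`). A SD incompatible with the Beta support falls back to a
clipped normal with a warning; a SD of zero pins the parameter. Draws
failing validation are excluded and counted rather than resampled, so
the draw stream is reproducible from `(seed, n)`. The
cost-effectiveness acceptability curve is, definitionally, the fraction
of retained draws with $\lambda\Delta E - \Delta C > 0$ on a grid of
101 points from 0 to 1.5× the upper threshold plus the exact
thresholds; ties at zero count as not cost-effective.

## Scenarios and subgroups

`scenario_spec()` declares overrides — discount 0%/5%, adherence
presets, a repeated-event risk multiplier on the chronic states, time
horizons, a trial-period hazard ratio on the intensive arm (0.68
emulates the older-patient effect seen in the other major intensive-BP
trial), risk-model substitution, cost multipliers, life-table
substitution — and `run_scenario()` applies them to a deep copy, so the
base bundle is provably untouched (`identical()` before and after is a
test). The packaged battery (`inst/extdata/scenarios.yaml`) holds
twelve scenarios; across the three countries that is the 36-run grid.

Subgroups (age 60–69 / 70–80, sex, enrollment-SBP bands, diabetes,
measurement type) are parameter sets, not code: a `subgroup_spec()`
carries its own rate table, profile tweaks and start age. The true
subgroup rates live in supplementary material we do not reproduce, so
`synthetic_subgroup_spec()` synthesizes plausible ones by scaling the
base rates with subgroup hazard multipliers. Start ages for the age
bands are not stated in the source; 65 and 75 are the defaults and are
recorded in the result's metadata.

## The synthetic input generator

`generate_inputs()` produces a complete, validated bundle with no
external data. What is real and what is synthetic:

- **Event rates**: the trial-period table verbatim — these are
  published numbers, not synthesized.
- **Life tables**: Gompertz, $q_x = 1 - \exp\{-a e^{b(\text{age}-60)}\}$
  with country-specific $(a, b)$ chosen once so that remaining life
  expectancy at 66 (and hence discounted lifetime QALY totals near
  9–12) sits in the range implied by the published lifetime results;
  China slightly heavier than the US and UK, matching the published
  observation that non-cardiovascular death was highest there.
- **Costs**: anchored to the order of magnitude readable from the
  published lifetime totals (e.g. Chinese lifetime totals around
  ¥100,000–¥120,000, US around $220,000, UK around £70,000), with a
  seeded 2% log-normal jitter so different seeds give distinct but
  equally plausible tables. Non-authoritative by construction.
- **Utilities**: baseline 0.80 at 66, age decrement 0.003/year, the
  post-stroke state worst among the chronic states (decrement 0.22) —
  consistent with stroke utility being a leading sensitivity driver.
- **Risk equation**: positive age and SBP log-hazards; the SBP
  coefficient is set to $-\ln(0.75)/9 \approx 0.032$ per mm Hg so the
  between-arm rate ratio over the trial's 9 mm Hg achieved-SBP gap
  stays continuous with the trial-observed relative risk (~0.75) when
  the extrapolation takes over; $S_0$ per country in 0.78–0.85, giving
  10-year composite risks that rise from ~20% at the cohort mean to
  well above 50% in the very old, the range SCORE2-OP-type equations
  produce in high-risk elderly hypertensives.

Because costs, utilities, life tables and coefficients are synthetic,
passing tests demonstrate that the *machinery* is right — mass
conservation, closed forms, oracle agreement, directional findings
(positive QALY gain, intervention cost as top tornado driver,
cost-effectiveness at the lower threshold) — not that the package
reproduces the published lifetime ICERs, PSA probabilities or
events-averted counts, which require the original supplementary
cost/utility tables and risk-equation calibrations. Supply those as
input files to attempt numerical reproduction.

## Validation and numerical choices

The one quantity reproducible from published inputs alone is the
trial-period incidence. Running the cohort for the 4-year window on the
trial rate table gives a primary-outcome incidence (first events per
100 person-years, mid-cycle timing: leavers contribute half a year)
of 0.990 intensive / 1.493 standard, against the published model's
1.14 / 1.39 and the trial's 1.00 / 1.40. The intensive-arm gap traces
to the published composite/person-year definition being under-specified
— the components of the trial table sum to about 0.99 per 100
person-years, below the published model's own 1.14 — so
`validate_trial_period()` treats agreement within ±0.15 per 100
person-years as a pass and reports the differences. Person-year timing
is switchable to full-cycle (`py_timing = "full"`).

Other numerical choices, in one place:

- cohort fractions are exact (the deterministic engine is primary);
  `cohort_size` only scales reported counts, and a seeded 200,000-person
  microsimulation exists in the test suite purely as an oracle, agreeing
  with the engine within 3 Monte Carlo SEs on 10-year occupancy;
- the trial table's SDs are treated as sampling SDs of the yearly
  probabilities (the PSA's Beta parameters) — the table does not say
  whether they are SDs or SEs;
- repeated cardiovascular risk in chronic states equals first-event
  risk by default (the source's stated assumption), exposed as a
  scenario multiplier;
- ages beyond the life table use the terminal rule (death probability
  1); a degenerate all-zero cardiovascular mix falls back to uniform
  shares (the composite is zero anyway);
- mass-conservation violations beyond 1e-10 per cycle raise an internal
  error rather than renormalizing.

Problem sizes used by the shipped tests — lifetime horizons of ~35
cycles, PSA draws of 200–1000, a 200,000-individual microsimulation,
4000-draw sampler checks — were chosen as the smallest sizes at which
the Monte Carlo assertions have comfortable power.

## Limitations

Kidney-disease progression is out of scope (as in the source model);
adverse-event probabilities are held at trial values after the trial
(exposed as `ae_post_multiplier`); parameters are drawn independently
in the PSA because no correlation structure is published; currency
conversion is a single display-layer purchasing-power-parity factor;
and no attempt is made to reverse-engineer the supplementary input
tables — the synthetic generator is labelled synthetic everywhere it
appears.
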