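Package: htncea
Title: Markov Cohort Cost-Effectiveness Analysis of Intensive Blood
    Pressure Control in Older Adults
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic Markov cohort model comparing intensive
    (110-130 mm Hg) and standard (130-150 mm Hg) systolic blood pressure
    targets in hypertensive adults aged 66 and over, from the health care
    payer perspective in China, the US and the UK. Yearly cycles track six
    health states plus cause-split death; trial-period transition
    probabilities hand over to proportional-hazards cardiovascular risk
    equations and national life tables for lifetime extrapolation, with
    medication-adherence blending. The package computes discounted costs
    and quality-adjusted life-years, incremental cost-effectiveness ratios
    and net monetary benefit, one-way (tornado) and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves,
    declarative scenario and subgroup batteries, trial-period validation
    against observed event incidence, and ships a seeded synthetic-input
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
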