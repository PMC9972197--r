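# Declarative scenario and subgroup runners. A scenario is a named set
# of overrides applied to a deep copy of the base inputs; the base bundle
# is never mutated.

#' Declare a scenario
#'
#' Unspecified fields inherit the base case. Supported overrides mirror
#' the study's scenario battery: discount rate (0%, 5%), adherence preset
#' or fractions, repeated-cardiovascular-event multiplier, time horizon,
#' trial-period treatment-effect hazard ratio on the intensive arm (e.g.
#' 0.68), risk-model substitution (a `risk_coefficients` object or a
#' coefficient file path), per-component cost multipliers, adverse-event
#' and cardiovascular risk multipliers, and a mortality-table
#' substitution.
#'
#' @param name Scenario name.
#' @param discount,adherence,repeat_cvd_multiplier,horizon Overrides.
#' @param treatment_effect_hr,risk_model,cost_multipliers Overrides.
#' @param ae_risk_multiplier,cv_risk_multiplier,life_table Overrides.
#' @return A list with class `scenario_spec`.
#' @export
scenario_spec <- function(name, discount = NULL, adherence = NULL,
                          repeat_cvd_multiplier = NULL, horizon = NULL,
                          treatment_effect_hr = NULL, risk_model = NULL,
                          cost_multipliers = NULL, ae_risk_multiplier = NULL,
                          cv_risk_multiplier = NULL, life_table = NULL) {
  structure(list(name = name, discount = discount, adherence = adherence,
                 repeat_cvd_multiplier = repeat_cvd_multiplier,
                 horizon = horizon, treatment_effect_hr = treatment_effect_hr,
                 risk_model = risk_model, cost_multipliers = cost_multipliers,
                 ae_risk_multiplier = ae_risk_multiplier,
                 cv_risk_multiplier = cv_risk_multiplier,
                 life_table = life_table),
            class = "scenario_spec")
}

.apply_scenario <- function(inputs, spec) {
  if (!is.null(spec$discount)) inputs$country$discount <- spec$discount
  if (!is.null(spec$adherence)) {
    inputs$adherence <- if (inherits(spec$adherence, "adherence_scenario")) {
      spec$adherence
    } else if (is.character(spec$adherence)) {
      adherence_scenario(spec$adherence)
    } else {
      adherence_scenario("custom", intensive = spec$adherence$intensive,
                         standard = spec$adherence$standard)
    }
  }
  for (k in c("repeat_cvd_multiplier", "treatment_effect_hr",
              "ae_post_multiplier", "cv_risk_multiplier")) {
    v <- spec[[sub("ae_post", "ae_risk", k)]]
    if (!is.null(v)) inputs$settings[[k]] <- v
  }
  if (!is.null(spec$risk_model)) {
    inputs$risk <- if (inherits(spec$risk_model, "risk_coefficients")) {
      spec$risk_model
    } else {
      load_risk_coefficients(spec$risk_model)
    }
    inputs$country$risk_model <- inputs$risk$model
  }
  if (!is.null(spec$cost_multipliers)) {
    for (comp in names(spec$cost_multipliers)) {
      f <- spec$cost_multipliers[[comp]]
      if (!comp %in% names(inputs$costs)) {
        .fail("scenario '", spec$name, "': unknown cost component '", comp, "'")
      }
      inputs$costs[[comp]] <- inputs$costs[[comp]] * f
    }
  }
  if (!is.null(spec$life_table)) {
    inputs$life_table <- if (is.character(spec$life_table)) {
      .read_csv(spec$life_table)
    } else as.data.frame(spec$life_table)
  }
  validate_model_inputs(inputs)
}

#' Run a scenario
#'
#' Applies the overrides to a copy of the base inputs, re-runs the full
#' two-arm pipeline and returns the cost-effectiveness result. The base
#' inputs are never modified. An empty spec reproduces the base case
#' exactly.
#'
#' @param base A [model_inputs()] bundle.
#' @param spec A [scenario_spec()].
#' @return A `ce_result` with the scenario name and horizon attached as
#'   attributes.
#' @export
run_scenario <- function(base, spec) {
  inputs <- .apply_scenario(base, spec)
  horizon <- spec$horizon %||% "lifetime"
  fit <- run_cea(inputs, horizon = horizon)
  structure(fit$result, scenario = spec$name, horizon = horizon)
}

#' Run the packaged scenario battery
#'
#' Reads a YAML list of scenario specs (default: the battery shipped
#' with the package, twelve scenarios mirroring the study's list) and
#' runs each against base inputs generated per country.
#'
#' @param inputs_by_country Named list of [model_inputs()] bundles (names
#'   are country codes); default generates synthetic inputs for CN, US
#'   and UK with `seed`.
#' @param file YAML battery file.
#' @param seed Seed for default synthetic inputs.
#' @return Data frame: one row per (country, scenario) with increments,
#'   ICER and events averted.
#' @export
run_scenario_battery <- function(inputs_by_country = NULL,
                                 file = system.file("extdata", "scenarios.yaml",
                                                    package = "htncea"),
                                 seed = 1) {
  if (is.null(inputs_by_country)) {
    cc <- c("CN", "US", "UK")
    inputs_by_country <- lapply(stats::setNames(cc, cc), function(co) {
      generate_inputs(synthetic_profile(co, seed = seed))
    })
  }
  specs <- lapply(yaml::read_yaml(file), function(s) do.call(scenario_spec, s))
  rows <- list()
  for (co in names(inputs_by_country)) {
    for (sp in specs) {
      r <- run_scenario(inputs_by_country[[co]], sp)
      rows[[length(rows) + 1L]] <- data.frame(
        country = co, scenario = sp$name, delta_cost = r$delta_cost,
        delta_qaly = r$delta_qaly, icer = r$icer, dominance = r$dominance,
        events_averted_per_1000 = r$events_averted_per_1000)
    }
  }
  do.call(rbind, rows)
}

# --- subgroups --------------------------------------------------------------

.SUBGROUPS <- c("age_60_69", "age_70_80", "sex_m", "sex_f", "sbp_le138",
                "sbp_139_151", "sbp_ge152", "diabetes_yes", "diabetes_no",
                "app_bp", "usual_bp")

#' Declare a subgroup
#'
#' A subgroup supplies its own event-rate table (both arms), optional
#' risk-profile overrides and an optional start age (age subgroups
#' default to 65 and 75).
#'
#' @param name One of the recognised stratifiers (see Details) or a free
#'   label.
#' @param rates Event-rate table for the subgroup (shape of
#'   [step_event_rates()]).
#' @param profile Optional named overrides of the cohort profile (`male`,
#'   `diabetes`, `smoking`, `sbp`).
#' @param start_age Optional start age.
#' @details Recognised stratifiers: age_60_69, age_70_80, sex_m, sex_f,
#'   sbp_le138, sbp_139_151, sbp_ge152, diabetes_yes, diabetes_no,
#'   app_bp, usual_bp.
#' @return A list with class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, rates, profile = NULL, start_age = NULL) {
  structure(list(name = name, rates = rates, profile = profile,
                 start_age = start_age), class = "subgroup_spec")
}

#' Run a subgroup analysis
#'
#' Swaps in the subgroup's event rates, profile and start age, then
#' re-runs the full pipeline. The base inputs are never modified.
#'
#' @param base A [model_inputs()] bundle.
#' @param spec A [subgroup_spec()].
#' @return A `ce_result` with the subgroup name attached.
#' @export
run_subgroup <- function(base, spec) {
  if (is.null(spec$rates)) .fail("subgroup '", spec$name, "': missing rate table")
  inputs <- base
  inputs$rates <- spec$rates
  for (k in names(spec$profile)) inputs$profile[[k]] <- spec$profile[[k]]
  if (!is.null(spec$start_age)) inputs$settings$start_age <- spec$start_age
  validate_model_inputs(inputs)
  structure(run_cea(inputs)$result, subgroup = spec$name,
            start_age = inputs$settings$start_age)
}

#' Synthesize subgroup parameter sets
#'
#' The study's subgroup-specific event rates live in supplementary
#' tables; this generator stands in for them by scaling the base rates
#' with subgroup-plausible hazard multipliers (e.g. higher cardiovascular
#' risk in men and in the highest enrollment-SBP band) and adjusting the
#' profile and start age. Synthetic, for harness testing — not study
#' estimates.
#'
#' @param base A [model_inputs()] bundle.
#' @param name A recognised stratifier (see [subgroup_spec()]).
#' @return A [subgroup_spec()].
#' @export
synthetic_subgroup_spec <- function(base, name) {
  if (!name %in% .SUBGROUPS) {
    .fail("unknown subgroup '", name, "'; recognised: ",
          paste(.SUBGROUPS, collapse = ", "))
  }
  mult <- switch(name,
    age_60_69 = 0.85, age_70_80 = 1.25, sex_m = 1.25, sex_f = 0.85,
    sbp_le138 = 0.85, sbp_139_151 = 1.00, sbp_ge152 = 1.20,
    diabetes_yes = 1.30, diabetes_no = 0.90, app_bp = 0.95, usual_bp = 1.05)
  rates <- base$rates
  cvrow <- rates$event %in% c("primary_composite", .CV_EVENTS)
  rates$mean[cvrow] <- rate_to_prob(prob_to_rate(rates$mean[cvrow]) * mult)
  prof <- switch(name,
    sex_m = list(male = 1), sex_f = list(male = 0),
    diabetes_yes = list(diabetes = 1), diabetes_no = list(diabetes = 0),
    sbp_le138 = list(sbp = base$profile$sbp - 8),
    sbp_ge152 = list(sbp = base$profile$sbp + 8),
    NULL)
  start_age <- switch(name, age_60_69 = 65, age_70_80 = 75, NULL)
  subgroup_spec(name, rates, profile = prof, start_age = start_age)
}

#' Run all recognised subgroups
#'
#' @param base A [model_inputs()] bundle.
#' @param names Subgroup names (default: all eleven stratifiers).
#' @return Data frame with one row per subgroup.
#' @export
run_subgroup_battery <- function(base, names = .SUBGROUPS) {
  rows <- lapply(names, function(nm) {
    r <- run_subgroup(base, synthetic_subgroup_spec(base, nm))
    data.frame(subgroup = nm, start_age = attr(r, "start_age"),
               delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
               icer = r$icer, dominance = r$dominance)
  })
  do.call(rbind, rows)
}
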