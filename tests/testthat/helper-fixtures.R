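# Shared fixtures, built in code. fixture_inputs() is cached per test run.

fixture_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_inputs(synthetic_profile("CN", seed = 1))
    }
    cache
  }
})

# minimal bundle: no events unless asked for, flat mortality, unit-ish
# utility, zero costs -- the closed-form workhorse
toy_inputs <- function(death_p = 0, utility = 1, discount = 0,
                       stroke_p = 0, max_age = 120, start_age = 66) {
  rates <- step_event_rates()
  rates$mean <- 0
  rates$sd <- 0
  rates$mean[rates$event == "all_cause_death"] <- death_p
  rates$mean[rates$event == "stroke"] <- stroke_p
  ev <- c(cv_events(), adverse_events())
  st <- health_states()[1:5]
  ages <- start_age:max_age
  model_inputs(
    rates = rates,
    costs = list(intervention = c(intensive = 0, standard = 0),
                 acute = stats::setNames(numeric(length(ev)), ev),
                 chronic = stats::setNames(numeric(4), st[2:5]),
                 background = 0),
    utilities = list(baseline = utility, age_decrement = 0,
                     state_decrement = stats::setNames(numeric(5), st),
                     event_decrement = stats::setNames(numeric(length(ev)), ev),
                     event_duration_weeks = stats::setNames(rep(2, length(ev)), ev)),
    adherence = adherence_scenario("base"),
    country = country_profile("CN", discount = discount),
    life_table = data.frame(age = ages,
                            qx = c(rep(death_p, length(ages) - 1), 1)),
    risk = risk_coefficients("null", data.frame(covariate = "sbp", beta = 0,
                                                mean = 130), s0 = 1),
    profile = list(male = 0.465, diabetes = 0.19, smoking = 0.2,
                   sbp = c(intensive = 127, standard = 136)),
    settings = list(start_age = start_age)
  )
}
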