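# Parameter bundle: constructors, validation, file ingestion and
# serialization. One `model_inputs` object holds everything a single
# country's two-arm run needs.

#' Built-in country profiles
#'
#' Discount rates, willingness-to-pay thresholds and currency conventions
#' for the three health systems covered by the analysis: China (3.0%
#' discount; WTP 1x and 3x GDP per capita, Y89,300 / Y267,900 per QALY),
#' the US (3.0%; $50,000 / $100,000) and the UK (3.5%; GBP 20,000 /
#' 30,000). `ppp_usd` is the multiplicative purchasing-power-parity factor
#' from local currency to US dollars, used for display only.
#'
#' @param country One of "CN", "US", "UK".
#' @param discount,wtp,ppp_usd,risk_model Optional overrides.
#' @return A list with class `country_profile`.
#' @examples
#' country_profile("UK")
#' @export
country_profile <- function(country = c("CN", "US", "UK"), discount = NULL,
                            wtp = NULL, ppp_usd = NULL, risk_model = NULL) {
  country <- match.arg(country)
  def <- switch(country,
    CN = list(currency = "CNY", discount = 0.03,
              wtp = c(lower = 89300, upper = 267900), ppp_usd = 1 / 4.18),
    US = list(currency = "USD", discount = 0.03,
              wtp = c(lower = 50000, upper = 100000), ppp_usd = 1),
    UK = list(currency = "GBP", discount = 0.035,
              wtp = c(lower = 20000, upper = 30000), ppp_usd = 1.497)
  )
  out <- list(
    country = country,
    currency = def$currency,
    discount = discount %||% def$discount,
    wtp = if (is.null(wtp)) def$wtp else c(lower = unname(wtp[[1]]), upper = unname(wtp[[2]])),
    ppp_usd = ppp_usd %||% def$ppp_usd,
    risk_model = risk_model %||% "synthetic"
  )
  if (out$discount < 0 || out$discount > 0.2) .fail("discount rate must lie in [0, 0.2]")
  if (out$wtp[["lower"]] >= out$wtp[["upper"]]) .fail("lower WTP must be below upper WTP")
  class(out) <- "country_profile"
  out
}

#' Adherence scenarios
#'
#' Fraction of each arm still at its blood-pressure target after the
#' 4-year trial period. Presets: base = (0.70, 0.75), worst = (0.00, 1.00),
#' best = (1.00, 0.75); `custom` takes explicit fractions.
#'
#' @param name One of "base", "worst", "best", "custom".
#' @param intensive,standard Adherent fractions in \eqn{[0,1]} (required for
#'   `custom`, ignored otherwise).
#' @return A list with class `adherence_scenario`.
#' @export
adherence_scenario <- function(name = c("base", "worst", "best", "custom"),
                               intensive = NULL, standard = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    base = c(0.70, 0.75), worst = c(0.00, 1.00), best = c(1.00, 0.75),
    custom = c(intensive %||% .fail("custom adherence needs `intensive`"),
               standard %||% .fail("custom adherence needs `standard`"))
  )
  if (any(preset < 0) || any(preset > 1)) .fail("adherent fractions must lie in [0, 1]")
  structure(list(name = name, intensive = preset[[1]], standard = preset[[2]]),
            class = "adherence_scenario")
}

.default_settings <- function() {
  list(start_age = 66, trial_years = 4, cohort_size = 10000,
       repeat_cvd_multiplier = 1, treatment_effect_hr = NULL,
       ae_post_multiplier = 1, cv_risk_multiplier = 1,
       half_cycle = FALSE, py_timing = "mid",
       cost_cv = 0.2, utility_cv = 0.1)
}

#' Assemble a full model-input bundle
#'
#' Collects every parameter one country/arm pair needs — yearly event
#' probabilities, costs, utilities, adherence, discounting, the all-cause
#' mortality life table and the post-trial cardiovascular risk equation —
#' into a single validated object consumed by [run_cohort()] and
#' [run_cea()].
#'
#' @param rates Data frame `event, arm, mean, sd, distribution` covering
#'   all of [rate_events()] for both arms (the shape of
#'   [step_event_rates()]).
#' @param costs List with `intervention` (named vector, per arm, yearly),
#'   `acute` (named vector per event, one-time), `chronic` (named vector
#'   per chronic state, yearly), `background` (yearly scalar).
#' @param utilities List with `baseline` (utility at the start age),
#'   `age_decrement` (per year of age), `state_decrement` (named vector per
#'   alive state), `event_decrement` and `event_duration_weeks` (named
#'   vectors per acute event).
#' @param adherence An [adherence_scenario()].
#' @param country A [country_profile()].
#' @param life_table Data frame `age, qx`; contiguous integer ages through
#'   a terminal age (>= 100) where `qx` is 1.
#' @param risk A coefficient set as returned by [risk_coefficients()] or
#'   [load_risk_coefficients()].
#' @param profile Baseline cohort covariates: list with `male`, `diabetes`,
#'   `smoking` (prevalences) and `sbp` (named vector of achieved systolic
#'   pressure per arm, mm Hg).
#' @param settings Optional overrides of engine settings (start age, trial
#'   years, scenario multipliers, PSA coefficients of variation, ...).
#' @return A list with class `model_inputs`, already validated.
#' @export
model_inputs <- function(rates, costs, utilities, adherence, country,
                         life_table, risk, profile, settings = list()) {
  s <- .default_settings()
  s[names(settings)] <- settings
  x <- structure(
    list(rates = rates, costs = costs, utilities = utilities,
         adherence = adherence, country = country, life_table = life_table,
         risk = risk, profile = profile, settings = s),
    class = "model_inputs")
  validate_model_inputs(x)
}

#' Validate a model-input bundle
#'
#' Checks every structural invariant (all thirteen event rows present for
#' both arms, probabilities in \eqn{[0,1]}, nonnegative SDs and costs,
#' utilities in \eqn{[0,1]}, decrement durations in (0, 52] weeks, life
#' table coverage and terminal rule, coefficient/covariate agreement) and
#' fails with a message naming the offending row or field.
#'
#' @param x A `model_inputs` object.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_model_inputs <- function(x) {
  r <- x$rates
  need <- c("event", "arm", "mean", "sd", "distribution")
  if (!all(need %in% names(r))) {
    .fail("rates table must have columns ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(r))) {
    id <- sprintf("rates row %d (%s, %s)", i, r$arm[i], r$event[i])
    if (!r$event[i] %in% .RATE_EVENTS) .fail(id, ": unknown event type")
    if (!r$arm[i] %in% .ARMS) .fail(id, ": unknown arm")
    if (!is.finite(r$mean[i]) || r$mean[i] < 0 || r$mean[i] > 1) {
      .fail(id, ": mean probability outside [0, 1]")
    }
    if (!is.finite(r$sd[i]) || r$sd[i] < 0) .fail(id, ": SD must be >= 0")
    if (!r$distribution[i] %in% c("beta", "log_normal")) {
      .fail(id, ": unknown distribution family '", r$distribution[i], "'")
    }
  }
  for (a in .ARMS) {
    miss <- setdiff(.RATE_EVENTS, r$event[r$arm == a])
    if (length(miss)) {
      .fail("rates table: arm '", a, "' is missing event(s) ",
            paste(miss, collapse = ", "))
    }
  }

  co <- x$costs
  if (!all(.ARMS %in% names(co$intervention))) {
    .fail("costs: `intervention` must name both arms")
  }
  allc <- c(co$intervention, co$acute, co$chronic, background = co$background)
  if (any(!is.finite(allc)) || any(allc < 0)) {
    bad <- names(allc)[!is.finite(allc) | allc < 0][1]
    .fail("costs: '", bad, "' must be a nonnegative number")
  }
  if (!x$country$currency %in% c("CNY", "USD", "GBP")) {
    .fail("currency must be one of CNY, USD, GBP")
  }

  u <- x$utilities
  uv <- c(baseline = u$baseline, age_decrement = u$age_decrement,
          u$state_decrement, u$event_decrement)
  if (any(!is.finite(uv)) || any(uv < 0) || any(uv > 1)) {
    bad <- names(uv)[!is.finite(uv) | uv < 0 | uv > 1][1]
    .fail("utilities: '", bad, "' must lie in [0, 1]")
  }
  dw <- u$event_duration_weeks[names(u$event_decrement)]
  dw <- dw[!is.na(dw)]
  if (any(dw <= 0) || any(dw > 52)) {
    .fail("utilities: event decrement durations must lie in (0, 52] weeks")
  }

  if (!inherits(x$adherence, "adherence_scenario")) {
    .fail("`adherence` must be an adherence_scenario()")
  }
  if (!inherits(x$country, "country_profile")) {
    .fail("`country` must be a country_profile()")
  }

  lt <- x$life_table
  if (!all(c("age", "qx") %in% names(lt))) .fail("life table needs columns age, qx")
  if (any(lt$qx < 0) || any(lt$qx > 1)) {
    .fail("life table: qx outside [0, 1] at age ", lt$age[lt$qx < 0 | lt$qx > 1][1])
  }
  if (any(diff(lt$age) != 1)) .fail("life table ages must be contiguous integers")
  if (max(lt$age) < 100) .fail("life table must reach a terminal age >= 100")
  if (lt$qx[nrow(lt)] != 1) .fail("life table terminal-age qx must be 1")
  if (min(lt$age) > x$settings$start_age) {
    .fail("life table must cover the start age ", x$settings$start_age)
  }

  .validate_risk(x$risk)
  p <- x$profile
  if (!all(.ARMS %in% names(p$sbp))) .fail("profile: `sbp` must name both arms")
  if (any(p$sbp < 80) || any(p$sbp > 250)) .fail("profile: SBP must lie in [80, 250] mm Hg")

  if (x$settings$start_age < 60) .fail("start age must be >= 60")
  if (!x$settings$py_timing %in% c("mid", "full")) {
    .fail("settings$py_timing must be 'mid' or 'full'")
  }
  invisible(x)
}

# --- file ingestion ---------------------------------------------------------

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

.parse_costs <- function(df, path) {
  get1 <- function(component, name = "", arm = "") {
    hit <- df$component == component &
      (name == "" | df$name == name) & (arm == "" | df$arm == arm)
    if (!any(hit)) {
      warning(sprintf("costs file %s: no '%s%s%s' entry; defaulting to 0",
                      basename(path), component,
                      if (nzchar(name)) paste0(":", name) else "",
                      if (nzchar(arm)) paste0(":", arm) else ""),
              call. = FALSE)
      return(0)
    }
    df$value[hit][1]
  }
  list(
    intervention = vapply(stats::setNames(.ARMS, .ARMS),
                          function(a) get1("intervention", arm = a), 0),
    acute = vapply(stats::setNames(c(.CV_EVENTS, .AE_EVENTS),
                                   c(.CV_EVENTS, .AE_EVENTS)),
                   function(e) get1("acute_event", name = e), 0),
    chronic = vapply(stats::setNames(.CHRONIC, .CHRONIC),
                     function(s) get1("chronic_state", name = s), 0),
    background = get1("background")
  )
}

.parse_utilities <- function(df, path) {
  pick <- function(component, name = "") {
    hit <- df$component == component & (name == "" | df$name == name)
    if (!any(hit)) return(NA_real_)
    df$value[hit][1]
  }
  ev <- c(.CV_EVENTS, .AE_EVENTS)
  dec <- vapply(stats::setNames(ev, ev),
                function(e) pick("event_decrement", e), 0)
  dur <- vapply(ev, function(e) {
    hit <- df$component == "event_decrement" & df$name == e
    if (!any(hit)) return(NA_real_)
    df$duration_weeks[hit][1]
  }, 0)
  miss <- is.na(dec)
  if (any(miss)) {
    warning(sprintf("utilities file %s: no decrement for %s; defaulting to 0",
                    basename(path), paste(ev[miss], collapse = ", ")),
            call. = FALSE)
    dec[miss] <- 0
    dur[miss] <- 2
  }
  st <- vapply(stats::setNames(.ALIVE, .ALIVE),
               function(s) pick("state_decrement", s), 0)
  st[is.na(st)] <- 0
  b <- pick("baseline")
  if (is.na(b)) .fail("utilities file ", basename(path), ": missing mandatory 'baseline' row")
  list(baseline = b,
       age_decrement = { a <- pick("age_decrement"); if (is.na(a)) 0 else a },
       state_decrement = st, event_decrement = dec,
       event_duration_weeks = stats::setNames(dur, ev))
}

#' Load model inputs from a configuration file
#'
#' Reads a YAML configuration naming the country, discounting, adherence
#' and cohort profile, plus the delimited parameter files it points at
#' (event-rate table, life table, costs, utilities, risk-equation
#' coefficients), and returns a validated [model_inputs()] bundle.
#' Relative file paths resolve against the configuration file's directory.
#' Missing optional cost or decrement entries default to 0 with a warning;
#' malformed mandatory entries are errors naming the offending row.
#'
#' @param config Path to a YAML configuration file.
#' @return A validated `model_inputs` object.
#' @seealso [write_model_inputs()] for the inverse, and
#'   [generate_inputs()] to synthesize a complete bundle.
#' @export
load_model_inputs <- function(config) {
  if (!file.exists(config)) .fail("config file not found: ", config)
  cfg <- yaml::read_yaml(config)
  dir <- dirname(normalizePath(config))
  f <- function(key) {
    p <- cfg$files[[key]]
    if (is.null(p)) .fail("config: missing mandatory files entry '", key, "'")
    if (!file.exists(p)) p <- file.path(dir, p)
    if (!file.exists(p)) .fail("config: file for '", key, "' not found: ", cfg$files[[key]])
    p
  }
  for (k in c("country", "adherence")) {
    if (is.null(cfg[[k]])) .fail("config: missing mandatory field '", k, "'")
  }
  country <- country_profile(cfg$country, discount = cfg$discount,
                             wtp = cfg$wtp, ppp_usd = cfg$ppp_usd,
                             risk_model = cfg$risk_model)
  adh <- adherence_scenario(cfg$adherence$name %||% "custom",
                            intensive = cfg$adherence$intensive,
                            standard = cfg$adherence$standard)
  prof <- list(
    male = cfg$profile$male %||% 0.465,
    diabetes = cfg$profile$diabetes %||% 0.19,
    smoking = cfg$profile$smoking %||% 0.20,
    sbp = c(intensive = cfg$profile$sbp$intensive %||% 127,
            standard = cfg$profile$sbp$standard %||% 136)
  )
  model_inputs(
    rates = .read_csv(f("rates")),
    costs = .parse_costs(.read_csv(f("costs")), f("costs")),
    utilities = .parse_utilities(.read_csv(f("utilities")), f("utilities")),
    adherence = adh,
    country = country,
    life_table = .read_csv(f("life_table")),
    risk = load_risk_coefficients(f("risk_coefficients")),
    profile = prof,
    settings = cfg$settings %||% list()
  )
}

# format doubles so read.csv round-trips them exactly
.fmt <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Serialize model inputs to a directory of plain-text files
#'
#' Writes the YAML configuration and the five delimited parameter files
#' that [load_model_inputs()] reads. Numeric fields are written with
#' enough digits that a load/write cycle is lossless.
#'
#' @param x A `model_inputs` object.
#' @param dir Output directory (created if needed).
#' @return Path to the written `config.yaml`, invisibly.
#' @export
write_model_inputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    df[] <- lapply(df, .fmt)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
    name
  }
  wcsv(x$rates, "rates.csv")
  wcsv(x$life_table, "life_table.csv")
  co <- x$costs
  costs_df <- rbind(
    data.frame(component = "intervention", name = "", arm = .ARMS,
               value = unname(co$intervention[.ARMS])),
    data.frame(component = "acute_event", name = names(co$acute), arm = "",
               value = unname(co$acute)),
    data.frame(component = "chronic_state", name = names(co$chronic), arm = "",
               value = unname(co$chronic)),
    data.frame(component = "background", name = "", arm = "",
               value = co$background)
  )
  wcsv(costs_df, "costs.csv")
  u <- x$utilities
  util_df <- rbind(
    data.frame(component = "baseline", name = "", value = u$baseline,
               duration_weeks = NA_real_),
    data.frame(component = "age_decrement", name = "", value = u$age_decrement,
               duration_weeks = NA_real_),
    data.frame(component = "state_decrement", name = names(u$state_decrement),
               value = unname(u$state_decrement), duration_weeks = NA_real_),
    data.frame(component = "event_decrement", name = names(u$event_decrement),
               value = unname(u$event_decrement),
               duration_weeks = unname(u$event_duration_weeks[names(u$event_decrement)]))
  )
  wcsv(util_df, "utilities.csv")
  write_risk_coefficients(x$risk, file.path(dir, "risk_coefficients.csv"))
  cfg <- list(
    country = x$country$country,
    discount = x$country$discount,
    wtp = as.list(x$country$wtp),
    ppp_usd = x$country$ppp_usd,
    risk_model = x$country$risk_model,
    adherence = list(name = x$adherence$name,
                     intensive = x$adherence$intensive,
                     standard = x$adherence$standard),
    profile = list(male = x$profile$male, diabetes = x$profile$diabetes,
                   smoking = x$profile$smoking,
                   sbp = as.list(x$profile$sbp)),
    settings = x$settings[!vapply(x$settings, is.null, TRUE)],
    files = list(rates = "rates.csv", life_table = "life_table.csv",
                 costs = "costs.csv", utilities = "utilities.csv",
                 risk_coefficients = "risk_coefficients.csv")
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.model_inputs <- function(x, ...) {
  cat(sprintf("<model_inputs> %s (%s), discount %.1f%%, adherence '%s' (%.0f%%/%.0f%%)\n",
              x$country$country, x$country$currency, 100 * x$country$discount,
              x$adherence$name, 100 * x$adherence$intensive,
              100 * x$adherence$standard))
  cat(sprintf("  start age %d, trial period %d y, life table to age %d, risk model '%s'\n",
              x$settings$start_age, x$settings$trial_years,
              max(x$life_table$age), x$risk$model))
  invisible(x)
}
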