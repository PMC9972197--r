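# Post-trial extrapolation: proportional-hazards cardiovascular risk
# equations, life-table competing mortality, and adherence blending.

#' Construct a cardiovascular risk-equation coefficient set
#'
#' Generic proportional-hazards form used by SCORE2-style equations:
#' 10-year risk \eqn{= 1 - S_0^{\exp(\sum_j \beta_j (x_j - \bar x_j))}}
#' times a calibration scale. Coefficients are data, not code: published
#' SCORE2 / SCORE2-OP / China-PAR / pooled-cohort-equation files can be
#' supplied in the same schema.
#'
#' @param model Model name (free text; "synthetic" for generated sets).
#' @param coef Data frame `covariate, beta, mean` with per-covariate
#'   log-hazard coefficients and cohort means.
#' @param s0 Baseline 10-year survival in (0, 1].
#' @param scale Multiplicative calibration factor (>= 0).
#' @return A list with class `risk_coefficients`.
#' @export
risk_coefficients <- function(model, coef, s0, scale = 1) {
  x <- structure(list(model = model, coef = coef, s0 = s0, scale = scale),
                 class = "risk_coefficients")
  .validate_risk(x)
  x
}

.validate_risk <- function(x) {
  if (!all(c("covariate", "beta", "mean") %in% names(x$coef))) {
    .fail("risk coefficients need columns covariate, beta, mean")
  }
  if (anyDuplicated(x$coef$covariate)) .fail("risk coefficients: duplicated covariate")
  if (!is.finite(x$s0) || x$s0 <= 0 || x$s0 > 1) {
    .fail("risk coefficients: baseline survival s0 must lie in (0, 1]")
  }
  if (!is.finite(x$scale) || x$scale < 0) .fail("risk coefficients: scale must be >= 0")
  invisible(x)
}

#' Read / write risk-equation coefficient files
#'
#' Plain CSV with `# key: value` metadata header lines (`model`, `s0`,
#' `scale`) followed by `covariate,beta,mean` rows.
#'
#' @param path File path.
#' @param x A `risk_coefficients` object (for writing).
#' @return `load_risk_coefficients()`: a `risk_coefficients` object;
#'   `write_risk_coefficients()`: `path`, invisibly.
#' @export
load_risk_coefficients <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    hit <- grep(sprintf("^#\\s*%s\\s*:", key), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", hit[1])
  }
  coef <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                            value = TRUE), collapse = "\n"),
                          stringsAsFactors = FALSE)
  risk_coefficients(
    model = get("model", "synthetic"),
    coef = coef,
    s0 = as.numeric(get("s0") %||% .fail("coefficient file ", path, ": missing '# s0:' header")),
    scale = as.numeric(get("scale", "1"))
  )
}

#' @rdname load_risk_coefficients
#' @export
write_risk_coefficients <- function(x, path) {
  hdr <- c(sprintf("# model: %s", x$model),
           sprintf("# s0: %.17g", x$s0),
           sprintf("# scale: %.17g", x$scale))
  df <- x$coef
  df$beta <- sprintf("%.17g", df$beta)
  df$mean <- sprintf("%.17g", df$mean)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a covariate profile for the risk equation
#'
#' @param age Age in years (>= 60).
#' @param sbp Achieved systolic blood pressure, mm Hg.
#' @param male,diabetes,smoking Indicator values (cohort-level fractions
#'   are accepted for a deterministic cohort).
#' @return Named list of covariate values with class `risk_profile`.
#' @export
risk_profile <- function(age, sbp, male = 0, diabetes = 0, smoking = 0) {
  if (age < 60) .fail("risk profile: age must be >= 60")
  if (sbp < 80 || sbp > 250) .fail("risk profile: SBP must lie in [80, 250] mm Hg")
  structure(list(age = age, sbp = sbp, male = male, diabetes = diabetes,
                 smoking = smoking), class = "risk_profile")
}

#' 10-year cardiovascular risk from a proportional-hazards equation
#'
#' Evaluates \eqn{1 - S_0^{\exp(\sum_j \beta_j (x_j - \bar x_j))}} and
#' applies the calibration scale, clamped to \eqn{[0, 1]}.
#'
#' @param profile A [risk_profile()] (any named list of covariate values).
#' @param coefficients A [risk_coefficients()] set.
#' @return 10-year event probability.
#' @export
ten_year_cvd_risk <- function(profile, coefficients) {
  cf <- coefficients$coef
  vals <- vapply(cf$covariate, function(v) {
    x <- profile[[v]]
    if (is.null(x)) .fail("risk profile is missing covariate '", v, "'")
    as.numeric(x)
  }, 0)
  lp <- sum(cf$beta * (vals - cf$mean))
  risk <- (1 - coefficients$s0^exp(lp)) * coefficients$scale
  min(max(risk, 0), 1)
}

#' Split a 10-year composite risk into yearly per-event probabilities
#'
#' Annualizes the composite (10-year to 1-year under constant hazard),
#' then distributes the yearly composite rate across event types by the
#' given shares; per-event rates sum exactly to the composite rate.
#'
#' @param ten_year_risk Composite 10-year probability.
#' @param event_mix Named nonnegative shares summing to 1.
#' @return Named vector of yearly per-event probabilities, with the yearly
#'   composite probability as attribute `composite`.
#' @export
annualize_composite_risk <- function(ten_year_risk, event_mix) {
  if (any(event_mix < 0)) .fail("event-mix shares must be nonnegative")
  if (abs(sum(event_mix) - 1) > 1e-9) .fail("event-mix shares must sum to 1")
  r <- prob_to_rate(ten_year_risk, 10)
  out <- rate_to_prob(r * event_mix, 1)
  attr(out, "composite") <- rate_to_prob(r, 1)
  out
}

#' Blend on-target and off-target event probabilities by adherence
#'
#' Mixes the two probabilities in rate space:
#' \eqn{1 - \exp(-(a r_{on} + (1-a) r_{off}))} with
#' \eqn{r = -\ln(1-p)}. Used after the trial period, where only the
#' adherent fraction of an arm retains that arm's event rates.
#'
#' @param p_on_target,p_off_target Yearly probabilities in \eqn{[0, 1)};
#'   vectorised.
#' @param adherent_fraction Fraction `a` in \eqn{[0, 1]}.
#' @return Blended yearly probability, always between the two anchors.
#' @export
blend_adherence <- function(p_on_target, p_off_target, adherent_fraction) {
  if (adherent_fraction < 0 || adherent_fraction > 1) {
    .fail("adherent fraction must lie in [0, 1]")
  }
  r <- adherent_fraction * prob_to_rate(p_on_target) +
    (1 - adherent_fraction) * prob_to_rate(p_off_target)
  rate_to_prob(r)
}

#' Non-cardiovascular death probability from a life table
#'
#' Subtracts the modeled cardiovascular death rate from the all-cause
#' life-table rate (competing risk in rate space) and back-transforms.
#' Floored at 0 with a warning if the modeled cardiovascular rate exceeds
#' the all-cause rate. Ages beyond the table use the terminal rule
#' (death probability 1).
#'
#' @param age Age in completed years.
#' @param life_table Data frame `age, qx`.
#' @param modeled_cv_death Yearly cardiovascular death probability already
#'   produced by the model.
#' @return Yearly non-cardiovascular death probability.
#' @export
noncvd_death_prob <- function(age, life_table, modeled_cv_death = 0) {
  qx <- lookup_qx(age, life_table)
  if (qx >= 1) return(1)
  d <- prob_to_rate(qx) - prob_to_rate(modeled_cv_death)
  if (d < 0) {
    warning(sprintf(
      "modeled CV death rate exceeds all-cause rate at age %d; flooring non-CVD death at 0",
      age), call. = FALSE)
    d <- 0
  }
  rate_to_prob(d)
}

#' Look up the all-cause yearly death probability at an age
#'
#' @inheritParams noncvd_death_prob
#' @return `qx` at `age`; 1 beyond the table's terminal age.
#' @export
lookup_qx <- function(age, life_table) {
  if (age > max(life_table$age)) return(1)
  if (age < min(life_table$age)) .fail("age ", age, " below life-table range")
  life_table$qx[match(age, life_table$age)]
}
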