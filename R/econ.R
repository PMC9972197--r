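# Discounting, per-cycle cost/QALY accrual, and incremental
# cost-effectiveness summaries.

#' Discount factor for a cycle
#'
#' \eqn{(1 + r)^{-k}} for cycle index `k` (0 for the first model year, so
#' costs and QALYs accrued in year one are undiscounted).
#'
#' @param rate Yearly discount rate (>= 0).
#' @param cycle Cycle index (>= 0); vectorised.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) .fail("discount rate must be >= 0")
  if (any(cycle < 0)) .fail("cycle index must be >= 0")
  (1 + rate)^(-cycle)
}

#' Accrue one cycle's cost and QALY
#'
#' Cost = occupancy x (chronic-state + background + intervention costs)
#' plus incident events x one-time acute costs. QALY = occupancy x
#' age-adjusted state utility minus incident events x decrement x
#' (duration in weeks / 52); acute decrements apply only in the event
#' cycle. State utility is `baseline - age_decrement x (age - start_age)
#' - state_decrement`, floored at 0. Both accruals are also returned
#' discounted with [discount_factor()] at `cycle - 1`.
#'
#' @param occupancy Named state-occupancy fractions at the start of the
#'   cycle (order of [health_states()]).
#' @param events Named incident event fractions (per patient) for the
#'   cycle.
#' @param age,cycle Age and 1-based cycle index.
#' @param costs,utilities Cost and utility components of a
#'   [model_inputs()] bundle.
#' @param discount_rate Yearly discount rate.
#' @param start_age Cohort start age (anchor of the age decrement).
#' @param intervention_cost Effective yearly intervention cost applied to
#'   the alive occupancy this cycle.
#' @return Named vector `cost`, `qaly`, `cost_disc`, `qaly_disc`
#'   (per patient).
#' @export
accrue_cycle <- function(occupancy, events, age, cycle, costs, utilities,
                         discount_rate = 0, start_age = 66,
                         intervention_cost = 0) {
  alive <- occupancy[.ALIVE]
  u_state <- pmax(0, utilities$baseline -
                    utilities$age_decrement * (age - start_age) -
                    utilities$state_decrement[.ALIVE])
  ev <- events[names(events) %in% names(costs$acute)]
  qaly <- sum(alive * u_state) -
    sum(events[names(utilities$event_decrement)] *
          utilities$event_decrement *
          utilities$event_duration_weeks[names(utilities$event_decrement)] / 52,
        na.rm = TRUE)
  chronic_cost <- c(no_cvd = 0, costs$chronic[.CHRONIC])
  cost <- sum(alive) * (costs$background + intervention_cost) +
    sum(alive * chronic_cost) +
    sum(ev * costs$acute[names(ev)])
  disc <- discount_factor(discount_rate, cycle - 1)
  c(cost = cost, qaly = qaly, cost_disc = cost * disc, qaly_disc = qaly * disc)
}

#' Incremental cost-effectiveness of intensive vs standard control
#'
#' Sums each arm's discounted costs and QALYs, forms the increments
#' (intensive minus standard), the ICER \eqn{\Delta C / \Delta E}, net
#' monetary benefit \eqn{\lambda \Delta E - \Delta C} at the country's
#' willingness-to-pay thresholds, and cardiovascular events averted per
#' 1000 patients. When \eqn{\Delta E = 0} the ICER is undefined and
#' flagged instead of divided; a negative \eqn{\Delta C} with positive
#' \eqn{\Delta E} is flagged as dominant (cost saving).
#'
#' @param trace_int,trace_std `cohort_trace` objects for the two arms,
#'   built from the same horizon and country.
#' @param country A [country_profile()].
#' @return A list of class `ce_result`: per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer`, `dominance` ("none", "dominant", "dominated",
#'   "undefined"), `nmb` at the two thresholds, `events_averted_per_1000`.
#' @export
compute_ce <- function(trace_int, trace_std, country) {
  tot <- function(tr) c(cost = sum(tr$cost_disc), qaly = sum(tr$qaly_disc))
  ti <- tot(trace_int); ts <- tot(trace_std)
  dc <- ti[["cost"]] - ts[["cost"]]
  de <- ti[["qaly"]] - ts[["qaly"]]
  dominance <- if (de == 0) {
    "undefined"
  } else if (de > 0 && dc <= 0) {
    "dominant"
  } else if (de < 0 && dc >= 0) {
    "dominated"
  } else "none"
  icer <- if (de != 0) dc / de else NA_real_
  nmb <- country$wtp * de - dc
  structure(list(
    country = country,
    cost = c(intensive = ti[["cost"]], standard = ts[["cost"]]),
    qaly = c(intensive = ti[["qaly"]], standard = ts[["qaly"]]),
    delta_cost = dc, delta_qaly = de, icer = icer, dominance = dominance,
    nmb = nmb,
    events_averted_per_1000 = events_averted(trace_int, trace_std)),
    class = "ce_result")
}

#' Cardiovascular events averted by intensive control
#'
#' Difference in cumulative cardiovascular events (all six types,
#' including repeats) between the standard and intensive arms, scaled per
#' `per` patients.
#'
#' @inheritParams compute_ce
#' @param per Reporting denominator (default 1000 patients).
#' @return Events averted per `per` patients (positive when intensive
#'   prevents events).
#' @export
events_averted <- function(trace_int, trace_std, per = 1000) {
  cum <- function(tr) {
    sum(as.data.frame(tr)[, paste0("ev_", .CV_EVENTS)]) / attr(tr, "cohort_size")
  }
  (cum(trace_std) - cum(trace_int)) * per
}

#' @export
print.ce_result <- function(x, ...) {
  cur <- x$country$currency
  cat(sprintf("<ce_result> %s, intensive vs standard BP control\n",
              x$country$country))
  cat(sprintf("  QALYs: %.3f vs %.3f  (delta %+.4f)\n",
              x$qaly[["intensive"]], x$qaly[["standard"]], x$delta_qaly))
  cat(sprintf("  Costs: %s%.0f vs %s%.0f  (delta %+.0f)\n", cur,
              x$cost[["intensive"]], cur, x$cost[["standard"]], x$delta_cost))
  if (x$dominance == "undefined") {
    cat("  ICER: undefined (no QALY difference)\n")
  } else if (x$dominance == "dominant") {
    cat("  Intensive dominates (more QALYs, lower cost)\n")
  } else {
    cat(sprintf("  ICER: %s%s per QALY gained%s\n", cur,
                format(round_half_away(x$icer), big.mark = ","),
                if (x$dominance == "dominated") " (dominated)" else ""))
  }
  cat(sprintf("  NMB at WTP %s%s / %s%s: %+.0f / %+.0f\n", cur,
              format(x$country$wtp[["lower"]], big.mark = ","), cur,
              format(x$country$wtp[["upper"]], big.mark = ","),
              x$nmb[["lower"]], x$nmb[["upper"]]))
  cat(sprintf("  CV events averted: %.0f per 1000 patients\n",
              x$events_averted_per_1000))
  invisible(x)
}

#' Serialize a cost-effectiveness result to JSON
#'
#' @param x A `ce_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ce_result <- function(x, path) {
  out <- list(country = x$country$country, currency = x$country$currency,
              cost = as.list(x$cost), qaly = as.list(x$qaly),
              delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
              icer = x$icer, dominance = x$dominance, nmb = as.list(x$nmb),
              events_averted_per_1000 = x$events_averted_per_1000)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
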