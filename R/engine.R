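# Yearly-cycle deterministic cohort engine. The cohort starts at the
# configured age with everyone event-free; cycles 1..trial_years use the
# trial-period transition probabilities, later cycles the risk-equation /
# life-table extrapolation with adherence blending.

# per-(arm, cycle) probability tables; rows = cycles
.arm_tables <- function(inputs, arm, n_cycles) {
  s <- inputs$settings
  rt <- inputs$rates
  get <- function(a, e) rt$mean[rt$arm == a & rt$event == e][1]
  getv <- function(a, ev) vapply(ev, function(e) get(a, e), 0)

  ages <- s$start_age + seq_len(n_cycles) - 1L
  phases <- ifelse(seq_len(n_cycles) <= s$trial_years, "trial", "post_trial")

  # --- trial phase -----------------------------------------------------
  own_cv <- getv(arm, .CV_EVENTS)
  std_cv <- getv("standard", .CV_EVENTS)
  trial_cv <- own_cv
  hr <- s$treatment_effect_hr
  if (!is.null(hr) && arm == "intensive") {
    # treatment-effect scenario: intensive trial-period CV rates replaced
    # by standard rates scaled with the hazard ratio
    trial_cv <- rate_to_prob(prob_to_rate(std_cv) * hr)
  }
  trial_ae <- getv(arm, .AE_EVENTS)
  # non-CVD death: all-cause net of CV death, in rate space
  trial_ncv <- rate_to_prob(max(0, prob_to_rate(get(arm, "all_cause_death")) -
                                  prob_to_rate(get(arm, "cv_death"))))

  # --- post-trial phase ------------------------------------------------
  # arm-specific case mix of the six CV event types, in rate space
  mix <- function(p6) {
    r <- prob_to_rate(p6)
    # degenerate all-zero case mix: shares are irrelevant (composite 0)
    if (sum(r) <= 0) return(stats::setNames(rep(1 / 6, 6), names(p6)))
    r / sum(r)
  }
  model_probs <- function(a, age) {
    pr <- risk_profile(age = min(age, 110), sbp = inputs$profile$sbp[[a]],
                       male = inputs$profile$male,
                       diabetes = inputs$profile$diabetes,
                       smoking = inputs$profile$smoking)
    r10 <- ten_year_cvd_risk(pr, inputs$risk)
    r10 <- rate_to_prob(prob_to_rate(min(r10, 1 - 1e-12), 10) *
                          s$cv_risk_multiplier, 10)
    annualize_composite_risk(r10, mix(getv(a, .CV_EVENTS)))
  }
  adh <- inputs$adherence[[arm]]
  post_cv <- matrix(0, n_cycles, 6L, dimnames = list(NULL, .CV_EVENTS))
  post_ncv <- numeric(n_cycles)
  post <- which(phases == "post_trial")
  for (k in post) {
    p_own <- model_probs(arm, ages[k])
    # the non-adherent fraction reverts to standard-target event rates
    p_eff <- if (arm == "standard") p_own else {
      blend_adherence(p_own, model_probs("standard", ages[k]), adh)
    }
    post_cv[k, ] <- p_eff
    post_ncv[k] <- noncvd_death_prob(ages[k], inputs$life_table,
                                     modeled_cv_death = p_eff[["cv_death"]])
  }
  post_ae <- rate_to_prob(prob_to_rate(trial_ae) * s$ae_post_multiplier)

  cv <- matrix(rep(trial_cv, each = n_cycles), n_cycles, 6L,
               dimnames = list(NULL, .CV_EVENTS))
  cv[post, ] <- post_cv[post, , drop = FALSE]
  ae <- matrix(rep(trial_ae, each = n_cycles), n_cycles, 5L,
               dimnames = list(NULL, .AE_EVENTS))
  ae[post, ] <- matrix(rep(post_ae, each = length(post)), length(post), 5L)
  ncv <- ifelse(phases == "trial", trial_ncv, post_ncv)
  # chronic-state (repeat-event) CV probabilities
  cv_rep <- rate_to_prob(prob_to_rate(cv) * s$repeat_cvd_multiplier)

  list(ages = ages, phases = phases, cv = cv, cv_rep = cv_rep, ae = ae,
       ncv = ncv)
}

#' Per-cycle transition probabilities for one state
#'
#' Yearly event probabilities faced by occupants of `state` at `age`:
#' during the trial phase these are the trial-period probabilities
#' verbatim; post-trial, cardiovascular events come from the risk
#' equation (split by the arm's trial case mix and blended by adherence)
#' and non-cardiovascular death from the life table net of modeled
#' cardiovascular death. Chronic states carry the repeat-event
#' multiplier. Absorbing states return all-zero probabilities.
#'
#' @param state A label from [health_states()].
#' @param age Age in years at the start of the cycle.
#' @param arm "intensive" or "standard".
#' @param inputs A [model_inputs()] bundle.
#' @param phase "trial" or "post_trial".
#' @return List with `cv` (named, six events incl. cardiovascular death),
#'   `ae` (five adverse events), `noncv_death`, and `stay` (probability of
#'   remaining in `state` with no event).
#' @export
cycle_probabilities <- function(state, age, arm, inputs,
                                phase = c("trial", "post_trial")) {
  phase <- match.arg(phase)
  state <- match.arg(state, .STATES)
  arm <- match.arg(arm, .ARMS)
  zero <- list(cv = stats::setNames(numeric(6), .CV_EVENTS),
               ae = stats::setNames(numeric(5), .AE_EVENTS),
               noncv_death = 0, stay = 1)
  if (state %in% c("dead_cv", "dead_noncv")) return(zero)
  s <- inputs$settings
  if (age < s$start_age) .fail("age must be >= the start age")
  k <- age - s$start_age + 1L
  if (phase == "post_trial" && k <= s$trial_years) {
    k <- s$trial_years + 1L  # phase overrides the cycle index
  }
  tab <- .arm_tables_cached(inputs, arm, max(k, 1L))
  if (phase == "trial") k <- min(k, s$trial_years)
  cvp <- if (state == "no_cvd") tab$cv[k, ] else tab$cv_rep[k, ]
  out <- list(cv = cvp, ae = tab$ae[k, ], noncv_death = tab$ncv[[k]])
  surv <- 1 - cvp[["cv_death"]] - out$noncv_death
  out$stay <- max(0, surv * (1 - sum(cvp[.CV_NONFATAL])))
  out
}

# cycle_probabilities is called one state/age at a time; rebuilding the
# table each call is cheap but avoidable for tight loops
.arm_tables_cached <- function(inputs, arm, n_cycles) {
  .arm_tables(inputs, arm, n_cycles)
}

# core mass update for one cycle.
# o: 7-vector; pcv: 5x6 matrix (rows alive states, cols .CV_EVENTS);
# pncv: length-5; pae: 5x5. Order of resolution: death, CV events among
# survivors, adverse events (state preserving).
.step_core <- function(o, pcv, pncv, pae) {
  m <- o[1:5]
  dcv <- m * pcv[, 6L]
  # non-CVD death competes on the mass surviving CV death, so a
  # terminal-age qx of 1 cleanly extinguishes the cohort
  dncv <- (m - dcv) * pncv
  surv <- m - dcv - dncv
  ev <- surv * pcv[, 1:5, drop = FALSE]
  stay <- surv - rowSums(ev)
  if (any(surv < -1e-12) || any(stay < -1e-12)) {
    .fail("internal: negative cohort mass; transition probabilities are inconsistent")
  }
  new_alive <- stay
  dest <- match(.CV_DEST[.CV_NONFATAL], .ALIVE)
  for (j in 1:5) new_alive[dest[j]] <- new_alive[dest[j]] + sum(ev[, j])
  aec <- colSums(surv * pae)
  events <- c(colSums(ev), cv_death = sum(dcv), aec, noncv_death = sum(dncv))
  list(
    occupancy = c(new_alive, o[6] + sum(dcv), o[7] + sum(dncv)),
    events = events,
    # first events: transitions out of the event-free state
    primary_first = dcv[1] + sum(ev[1, ]),
    leavers_no_cvd = dcv[1] + dncv[1] + sum(ev[1, ])
  )
}

#' Advance the cohort by one cycle
#'
#' Applies, in order: death (cardiovascular death plus non-cardiovascular
#' death), then one competing cardiovascular event among survivors
#' (multinomial built from the marginal yearly probabilities, residual =
#' no event, destinations: stroke to post-stroke, ACS and
#' revascularization to chronic CHD, acute HF to chronic HF, AF to
#' chronic AF), then adverse events, which preserve state and only accrue
#' costs and utility decrements. Mass is conserved.
#'
#' @param occupancy Named 7-vector of state occupancy fractions (order of
#'   [health_states()]) summing to 1.
#' @param probs Named list keyed by alive state; each element as returned
#'   by [cycle_probabilities()].
#' @return List with `occupancy` (next cycle), `events` (named incident
#'   fractions per event type), `primary_first` (first cardiovascular
#'   events, i.e. transitions out of the event-free state).
#' @export
step_cohort <- function(occupancy, probs) {
  if (abs(sum(occupancy) - 1) > 1e-8) .fail("occupancy must sum to 1")
  o <- as.numeric(occupancy[.STATES])
  pcv <- t(vapply(.ALIVE, function(s) probs[[s]]$cv[.CV_EVENTS], numeric(6)))
  pncv <- vapply(.ALIVE, function(s) probs[[s]]$noncv_death, 0)
  pae <- t(vapply(.ALIVE, function(s) probs[[s]]$ae[.AE_EVENTS], numeric(5)))
  out <- .step_core(o, pcv, pncv, pae)
  names(out$occupancy) <- .STATES
  out[c("occupancy", "events", "primary_first")]
}

#' Run the deterministic cohort simulation for one arm
#'
#' Propagates state-occupancy fractions cycle by cycle from the start age
#' until the horizon (or cohort extinction), accruing per-cycle costs and
#' QALYs (discounted and undiscounted), incident event counts, and
#' person-years at risk of a first cardiovascular event.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param arm "intensive" or "standard".
#' @param horizon `"lifetime"` (run to the life table's terminal age) or a
#'   whole number of years >= 1.
#' @param cohort_size Cohort size used to scale reported event counts and
#'   person-years (default from `inputs$settings`, 10,000).
#' @return A data frame of class `cohort_trace`, one row per cycle:
#'   `cycle`, `age`, `phase`, end-of-cycle occupancy fractions (`occ_*`),
#'   incident event counts per cohort (`ev_*`, including
#'   `ev_primary_first`), person-years at risk (`py_at_risk`, mid-cycle
#'   timing by default), and per-patient cost/QALY accruals (`cost`,
#'   `cost_disc`, `qaly`, `qaly_disc`). Run metadata is attached as
#'   attributes.
#' @export
run_cohort <- function(inputs, arm = c("intensive", "standard"),
                       horizon = "lifetime", cohort_size = NULL) {
  arm <- match.arg(arm)
  s <- inputs$settings
  cohort_size <- cohort_size %||% s$cohort_size
  terminal <- max(inputs$life_table$age)
  if (identical(horizon, "lifetime")) {
    n_cycles <- terminal - s$start_age + 1L
  } else {
    if (!is.numeric(horizon) || horizon < 1) .fail("horizon must be 'lifetime' or >= 1")
    n_cycles <- as.integer(horizon)
  }
  tab <- .arm_tables(inputs, arm, n_cycles)
  rep_chronic <- s$repeat_cvd_multiplier != 1
  d <- inputs$country$discount
  w_py <- if (s$py_timing == "mid") 0.5 else 0
  a_post <- if (arm == "intensive") inputs$adherence$intensive else 1
  c_int <- inputs$costs$intervention

  o <- c(1, numeric(6))
  rows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    age <- tab$ages[[k]]
    pcv <- rbind(tab$cv[k, ], tab$cv_rep[k, ], tab$cv_rep[k, ],
                 tab$cv_rep[k, ], tab$cv_rep[k, ])
    pae <- matrix(tab$ae[k, ], 5L, 5L, byrow = TRUE)
    st <- .step_core(o, pcv, rep(tab$ncv[[k]], 5), pae)
    # effective yearly intervention cost: post-trial, the non-adherent
    # intensive fraction is assumed back on standard-intensity treatment
    iw <- if (tab$phases[[k]] == "trial" || arm == "standard") {
      c_int[[arm]]
    } else {
      a_post * c_int[["intensive"]] + (1 - a_post) * c_int[["standard"]]
    }
    occ_acc <- if (isTRUE(s$half_cycle)) (o + st$occupancy) / 2 else o
    acc <- accrue_cycle(
      occupancy = stats::setNames(occ_acc, .STATES),
      events = st$events, age = age, cycle = k,
      costs = inputs$costs, utilities = inputs$utilities,
      discount_rate = d, start_age = s$start_age,
      intervention_cost = iw)
    py <- o[1] - w_py * st$leavers_no_cvd
    rows[[k]] <- c(cycle = k, age = age,
                   phase = if (tab$phases[[k]] == "trial") 1 else 0,
                   stats::setNames(st$occupancy, paste0("occ_", .STATES)),
                   stats::setNames(st$events * cohort_size,
                                   paste0("ev_", names(st$events))),
                   ev_primary_first = st$primary_first * cohort_size,
                   py_at_risk = py * cohort_size,
                   cost = acc[["cost"]], cost_disc = acc[["cost_disc"]],
                   qaly = acc[["qaly"]], qaly_disc = acc[["qaly_disc"]])
    o <- st$occupancy
    if (sum(o[1:5]) < 1e-9) { rows <- rows[seq_len(k)]; break }
  }
  tr <- as.data.frame(do.call(rbind, rows))
  tr$phase <- ifelse(tr$phase == 1, "trial", "post_trial")
  structure(tr, class = c("cohort_trace", "data.frame"),
            arm = arm, cohort_size = cohort_size, start_age = s$start_age,
            trial_years = s$trial_years, country = inputs$country$country,
            discount = d)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<cohort_trace> %s arm, %s, %d cycles (ages %d-%d), cohort %d\n",
              attr(x, "arm"), attr(x, "country"), n, x$age[1], x$age[n],
              attr(x, "cohort_size")))
  cat(sprintf("  alive at end: %.1f%%; totals: %.3f QALYs, %.0f cost (discounted, per patient)\n",
              100 * sum(x[n, paste0("occ_", .ALIVE)]),
              sum(x$qaly_disc), sum(x$cost_disc)))
  invisible(x)
}

#' Serialize a cohort trace to CSV
#'
#' @param x A `cohort_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
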