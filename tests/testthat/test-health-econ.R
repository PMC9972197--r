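test_that("discount factors follow (1+r)^-cycle", {
  expect_identical(discount_factor(0.03, 0), 1)
  expect_identical(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03, tolerance = 1e-12)
  expect_error(discount_factor(0.03, -1), ">= 0")
  expect_error(discount_factor(-0.01, 2), ">= 0")
})

test_that("cycle accrual prices occupancy and events correctly", {
  inp <- fixture_inputs()
  st <- health_states()
  dead <- stats::setNames(c(numeric(5), 0.4, 0.6), st)
  ev0 <- stats::setNames(numeric(11), c(cv_events(), adverse_events()))
  acc <- accrue_cycle(dead, ev0, age = 80, cycle = 10, costs = inp$costs,
                      utilities = inp$utilities, discount_rate = 0.03)
  expect_identical(unname(acc[c("cost", "qaly")]), c(0, 0))

  u <- inp$utilities
  u$baseline <- 0.8; u$age_decrement <- 0
  u$state_decrement[] <- 0
  co <- inp$costs
  co$intervention[] <- 0; co$acute[] <- 0; co$chronic[] <- 0; co$background <- 0
  full <- stats::setNames(c(1, numeric(6)), st)
  acc <- accrue_cycle(full, ev0, age = 66, cycle = 1, costs = co,
                      utilities = u, discount_rate = 0)
  expect_equal(acc[["qaly"]], 0.8, tolerance = 1e-12)

  # one fracture per person: decrement 0.2 for 12 of 52 weeks
  u$event_decrement[] <- 0
  u$event_decrement[["fracture"]] <- 0.2
  u$event_duration_weeks[["fracture"]] <- 12
  ev <- ev0; ev[["fracture"]] <- 1
  acc2 <- accrue_cycle(full, ev, age = 66, cycle = 1, costs = co,
                       utilities = u, discount_rate = 0)
  expect_equal(acc[["qaly"]] - acc2[["qaly"]], 0.2 * 12 / 52,
               tolerance = 1e-12)
})

test_that("increments are exact differences and identical arms are flagged", {
  inp <- fixture_inputs()
  ti <- run_cohort(inp, "intensive", horizon = 10)
  ts <- run_cohort(inp, "standard", horizon = 10)
  ce <- compute_ce(ti, ts, inp$country)
  expect_identical(ce$delta_cost,
                   ce$cost[["intensive"]] - ce$cost[["standard"]])
  expect_identical(ce$delta_qaly,
                   ce$qaly[["intensive"]] - ce$qaly[["standard"]])
  expect_equal(ce$icer, ce$delta_cost / ce$delta_qaly)

  same <- compute_ce(ts, ts, inp$country)
  expect_identical(same$delta_cost, 0)
  expect_identical(same$dominance, "undefined")
  expect_true(is.na(same$icer))
  expect_identical(events_averted(ts, ts), 0)
})

test_that("net monetary benefit changes sign exactly at the ICER", {
  inp <- fixture_inputs()
  fit <- run_cea(inp, horizon = 25)
  r <- fit$result
  stopifnot(r$delta_qaly > 0)
  for (lam in c(0.5, 0.99, 1.01, 3) * r$icer) {
    nmb <- lam * r$delta_qaly - r$delta_cost
    expect_identical(nmb > 0, r$icer < lam)
  }
})

test_that("a toy one-cycle model averts the probability difference", {
  hi <- toy_inputs(stroke_p = 0.10)
  lo <- toy_inputs(stroke_p = 0.05)
  t_hi <- run_cohort(hi, "standard", horizon = 1)
  t_lo <- run_cohort(lo, "standard", horizon = 1)
  expect_equal(events_averted(t_lo, t_hi), 50, tolerance = 1e-9)
})

test_that("half-away-from-zero rounding behaves at the boundary", {
  expect_identical(round_half_away(c(0.5, 1.5, -0.5, 2.4)), c(1, 2, -1, 2))
})
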