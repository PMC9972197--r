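test_that("trial-phase cycle probabilities are the trial table verbatim", {
  inp <- fixture_inputs()
  p <- cycle_probabilities("no_cvd", 66, "intensive", inp, "trial")
  expect_identical(p$cv[["stroke"]], 0.002840265)
  expect_identical(p$cv[["cv_death"]], 0.001062262)
  # non-CVD death is the rate-space residual of all-cause minus CV death
  expect_equal(p$noncv_death,
               1 - exp(-(-log(1 - 0.003971272) + log(1 - 0.001062262))),
               tolerance = 1e-12)
})

test_that("absorbing states emit no events and the terminal age kills", {
  inp <- fixture_inputs()
  p <- cycle_probabilities("dead_cv", 80, "standard", inp, "post_trial")
  expect_true(all(p$cv == 0) && all(p$ae == 0) && p$noncv_death == 0)
  expect_identical(p$stay, 1)
  p <- cycle_probabilities("no_cvd", 101, "intensive", inp, "post_trial")
  expect_identical(p$noncv_death, 1)
})

test_that("a cohort parked in death does not move", {
  inp <- fixture_inputs()
  occ <- stats::setNames(c(0, 0, 0, 0, 0, 0, 1), health_states())
  probs <- sapply(health_states()[1:5], function(s) {
    cycle_probabilities(s, 70, "standard", inp, "post_trial")
  }, simplify = FALSE)
  out <- step_cohort(occ, probs)
  expect_identical(out$occupancy, occ)
  expect_true(all(out$events == 0))
})

test_that("pure mortality decays geometrically", {
  inp <- toy_inputs(death_p = 0.1)
  probs <- sapply(health_states()[1:5], function(s) {
    cycle_probabilities(s, 66, "standard", inp, "trial")
  }, simplify = FALSE)
  occ <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), health_states())
  for (k in 1:5) {
    out <- step_cohort(occ, probs)
    occ <- out$occupancy
    expect_equal(occ[["no_cvd"]], 0.9^k, tolerance = 1e-12)
  }
})

test_that("one step from the event-free state matches hand multiplication", {
  inp <- fixture_inputs()
  tr <- run_cohort(inp, "standard", horizon = 1, cohort_size = 1)
  # oracle: death resolves first, events hit the surviving mass
  p_cvd <- 0.001467614
  p_ncv <- 1 - exp(-(-log(1 - 0.003770095) + log(1 - 0.001467614)))
  surv <- (1 - p_cvd) * (1 - p_ncv)
  expect_equal(tr$ev_stroke[1], surv * 0.004185055, tolerance = 1e-12)
  expect_equal(tr$ev_acs[1], surv * 0.004838185, tolerance = 1e-12)
  expect_equal(tr$ev_cv_death[1], p_cvd, tolerance = 1e-12)
})

test_that("mass is conserved and death is monotone over a lifetime run", {
  inp <- fixture_inputs()
  for (arm in arms()) {
    tr <- as.data.frame(run_cohort(inp, arm))
    occ <- tr[, paste0("occ_", health_states())]
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-10)
    dead <- tr$occ_dead_cv + tr$occ_dead_noncv
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(as.matrix(tr[, grep("^ev_", names(tr))]) >= 0))
  }
})

test_that("with no events the trace reproduces the life-table survival curve", {
  inp <- toy_inputs()
  inp$life_table <- generate_lifetable(0.01, 0.08, ages = 66:100)
  inp <- validate_model_inputs(inp)
  tr <- as.data.frame(run_cohort(inp, "intensive"))
  alive <- unname(rowSums(tr[, paste0("occ_", health_states()[1:5])]))
  # trial phase has zero all-cause probability; the life table takes over
  expect_equal(alive[1:4], rep(1, 4), tolerance = 1e-12)
  post <- 5:nrow(tr)
  expected <- cumprod(1 - inp$life_table$qx[match(tr$age[post],
                                                  inp$life_table$age)])
  expect_equal(alive[post], expected, tolerance = 1e-12)
})

test_that("raising one event probability cannot reduce that event's lifetime count", {
  inp <- fixture_inputs()
  base <- sum(run_cohort(inp, "standard")$ev_stroke)
  up <- perturb_parameter(inp, "rate:standard:stroke", 1.3)
  expect_gte(sum(run_cohort(up, "standard")$ev_stroke), base)
})

test_that("invalid horizons are rejected", {
  expect_error(run_cohort(fixture_inputs(), "intensive", horizon = 0), "horizon")
})
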