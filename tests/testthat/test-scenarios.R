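test_that("an empty scenario reproduces the base case and leaves inputs pure", {
  inp <- fixture_inputs()
  snapshot <- unserialize(serialize(inp, NULL))
  base <- run_cea(inp)$result
  r <- run_scenario(inp, scenario_spec("identity"))
  expect_equal(r$icer, base$icer, tolerance = 1e-12)
  expect_equal(r$delta_qaly, base$delta_qaly, tolerance = 1e-12)
  expect_identical(inp, snapshot)
})

test_that("removing discounting increases both arms' QALY totals", {
  inp <- fixture_inputs()
  base <- run_cea(inp)$result
  r0 <- run_scenario(inp, scenario_spec("discount_0", discount = 0))
  expect_gt(r0$qaly[["intensive"]], base$qaly[["intensive"]])
  expect_gt(r0$qaly[["standard"]], base$qaly[["standard"]])
  r5 <- run_scenario(inp, scenario_spec("discount_5", discount = 0.05))
  expect_lt(r5$qaly[["intensive"]], base$qaly[["intensive"]])
})

test_that("doubled repeat-event risk makes intensive control more favorable", {
  inp <- fixture_inputs()
  base <- run_cea(inp)$result
  r <- run_scenario(inp, scenario_spec("repeat_x2", repeat_cvd_multiplier = 2))
  expect_lt(r$icer, base$icer)
})

test_that("scenario overrides hit their parameter paths or fail by name", {
  inp <- fixture_inputs()
  r <- run_scenario(inp, scenario_spec("hr", treatment_effect_hr = 0.68,
                                       horizon = 10))
  expect_identical(attr(r, "scenario"), "hr")
  expect_error(
    run_scenario(inp, scenario_spec("bad", cost_multipliers = list(nope = 2))),
    "unknown cost component 'nope'")
  short <- run_scenario(inp, scenario_spec("h10", horizon = 10))
  expect_lt(short$qaly[["intensive"]], run_cea(inp)$result$qaly[["intensive"]])
})

test_that("the packaged battery runs one row per country-scenario pair", {
  cc <- c("CN", "UK")
  inputs <- sapply(cc, function(co) {
    generate_inputs(synthetic_profile(co, seed = 1))
  }, simplify = FALSE)
  batt <- run_scenario_battery(inputs)
  expect_identical(nrow(batt), 2L * 12L)
  expect_false(any(duplicated(batt[c("country", "scenario")])))
  expect_true(all(is.finite(batt$icer)))
})

test_that("subgroups with base parameters reproduce the base case", {
  inp <- fixture_inputs()
  base <- run_cea(inp)$result
  r <- run_subgroup(inp, subgroup_spec("copy", rates = inp$rates))
  expect_equal(r$icer, base$icer, tolerance = 1e-12)
  expect_error(run_subgroup(inp, subgroup_spec("none", rates = NULL)),
               "missing rate table")
})

test_that("subgroup direction checks: sex and age gradients", {
  inp <- fixture_inputs()
  m <- run_subgroup(inp, synthetic_subgroup_spec(inp, "sex_m"))
  f <- run_subgroup(inp, synthetic_subgroup_spec(inp, "sex_f"))
  expect_lt(m$icer, f$icer)  # higher male CV risk, lower ICER
  young <- run_subgroup(inp, synthetic_subgroup_spec(inp, "age_60_69"))
  old <- run_subgroup(inp, synthetic_subgroup_spec(inp, "age_70_80"))
  expect_lt(old$qaly[["intensive"]], young$qaly[["intensive"]])
  expect_error(synthetic_subgroup_spec(inp, "martians"), "unknown subgroup")
})
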