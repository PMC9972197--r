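synthetic_coefs <- function(beta_sbp = 0.02, s0 = 0.9, mean_sbp = 130) {
  risk_coefficients("synthetic",
                    data.frame(covariate = "sbp", beta = beta_sbp,
                               mean = mean_sbp), s0 = s0)
}

test_that("the proportional-hazards risk equation matches its closed form", {
  cf <- synthetic_coefs()
  prof <- risk_profile(age = 70, sbp = 130)
  expect_equal(ten_year_cvd_risk(prof, cf), 1 - 0.9) # linear predictor 0
  expect_identical(ten_year_cvd_risk(prof, synthetic_coefs(s0 = 1)), 0)
  # SBP 10 mm Hg above the mean: 1 - 0.9^exp(0.2)
  prof <- risk_profile(age = 70, sbp = 140)
  expect_equal(ten_year_cvd_risk(prof, cf), 1 - 0.9^exp(0.2),
               tolerance = 1e-12)
  expect_error(
    ten_year_cvd_risk(list(age = 70), fixture_inputs()$risk),
    "missing covariate 'sbp'")
})

test_that("doubling the calibration scale never lowers the risk", {
  inp <- fixture_inputs()
  for (sbp in c(120, 140, 160)) {
    prof <- risk_profile(age = 75, sbp = sbp, male = 1)
    cf2 <- inp$risk
    cf2$scale <- 2 * cf2$scale
    expect_gte(ten_year_cvd_risk(prof, cf2), ten_year_cvd_risk(prof, inp$risk))
  }
})

test_that("composite risk annualizes and splits with rate conservation", {
  mix <- c(stroke = 0.4, acs = 0.3, acute_hf = 0.1, revascularization = 0.1,
           af = 0.05, cv_death = 0.05)
  expect_true(all(annualize_composite_risk(0, mix) == 0))
  one <- annualize_composite_risk(0.10, c(stroke = 1))
  expect_equal(one[["stroke"]], 1 - exp(log(0.9) / 10), tolerance = 1e-12)
  for (risk in c(0.05, 0.2, 0.6)) {
    p <- annualize_composite_risk(risk, mix)
    expect_lt(abs(sum(prob_to_rate(p)) - prob_to_rate(attr(p, "composite"))),
              1e-12)
    pr <- prob_to_rate(p)
    expect_equal(c(pr / sum(pr)), mix, tolerance = 1e-9)
  }
  expect_error(annualize_composite_risk(0.1, c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("adherence blending interpolates in rate space", {
  expect_identical(blend_adherence(0.01, 0.05, 1), 0.01)
  expect_identical(blend_adherence(0.01, 0.05, 0), 0.05)
  r <- function(p) -log(1 - p)
  expect_equal(blend_adherence(0.0088, 0.0117, 0.70),
               1 - exp(-(0.7 * r(0.0088) + 0.3 * r(0.0117))),
               tolerance = 1e-12)
  # always between the anchors, monotone in the adherent fraction
  a <- seq(0, 1, by = 0.1)
  b <- vapply(a, function(x) blend_adherence(0.0088, 0.0117, x), 0)
  expect_true(all(b >= 0.0088 - 1e-15 & b <= 0.0117 + 1e-15))
  expect_true(all(diff(b) < 0))
})

test_that("non-CVD death subtracts competing CV mortality in rate space", {
  lt <- data.frame(age = 60:100, qx = c(rep(0.02, 40), 1))
  expect_identical(noncvd_death_prob(66, lt, 0), 0.02)
  r <- function(p) -log(1 - p)
  expect_equal(noncvd_death_prob(66, lt, 0.0015),
               1 - exp(-(r(0.02) - r(0.0015))), tolerance = 1e-12)
  expect_warning(p0 <- noncvd_death_prob(66, lt, 0.05), "flooring")
  expect_identical(p0, 0)
  expect_identical(noncvd_death_prob(150, lt, 0), 1)
})

test_that("coefficient files round-trip through their CSV schema", {
  cf <- fixture_inputs()$risk
  path <- tempfile(fileext = ".csv")
  write_risk_coefficients(cf, path)
  back <- load_risk_coefficients(path)
  expect_identical(back$model, cf$model)
  expect_equal(back$s0, cf$s0, tolerance = 1e-15)
  expect_equal(back$coef$beta, cf$coef$beta, tolerance = 1e-15)
})
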