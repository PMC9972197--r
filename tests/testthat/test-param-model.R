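fixture_config <- system.file("extdata", "synthetic-cn", "config.yaml",
                              package = "htncea")

test_that("the packaged configuration loads into a valid bundle", {
  inp <- load_model_inputs(fixture_config)
  expect_s3_class(inp, "model_inputs")
  r <- inp$rates
  expect_identical(
    r$mean[r$arm == "intensive" & r$event == "primary_composite"],
    0.008776182)
  expect_setequal(unique(r$event), rate_events())
  expect_identical(inp$country$discount, 0.03)
})

test_that("loading then re-serializing is lossless for numeric fields", {
  inp <- load_model_inputs(fixture_config)
  dir <- tempfile()
  back <- load_model_inputs(write_model_inputs(inp, dir))
  expect_equal(back$rates$mean, inp$rates$mean, tolerance = 1e-15)
  expect_equal(back$rates$sd, inp$rates$sd, tolerance = 1e-15)
  expect_equal(back$costs, inp$costs, tolerance = 1e-15)
  expect_equal(back$life_table, inp$life_table, tolerance = 1e-15)
  expect_equal(back$risk$coef, inp$risk$coef, tolerance = 1e-15)
  expect_equal(back$risk$s0, inp$risk$s0)
  expect_equal(back$utilities, inp$utilities, tolerance = 1e-15)
  expect_equal(back$country$discount, inp$country$discount)
  expect_equal(back$country$wtp, inp$country$wtp)
  expect_equal(back$adherence$intensive, inp$adherence$intensive)
})

test_that("validation errors name the offending row", {
  inp <- fixture_inputs()
  bad <- inp
  i <- which(bad$rates$arm == "standard" & bad$rates$event == "stroke")
  bad$rates$mean[i] <- 1.2
  expect_error(validate_model_inputs(bad), "standard, stroke.*outside \\[0, 1\\]")

  bad <- inp
  bad$rates <- bad$rates[-which(bad$rates$arm == "intensive" &
                                  bad$rates$event == "aki"), ]
  expect_error(validate_model_inputs(bad), "missing event.*aki")

  bad <- inp
  bad$rates$distribution[3] <- "uniform"
  expect_error(validate_model_inputs(bad), "unknown distribution")

  bad <- inp
  bad$costs$acute[["stroke"]] <- -5
  expect_error(validate_model_inputs(bad), "stroke.*nonnegative")

  bad <- inp
  bad$utilities$event_duration_weeks[["fracture"]] <- 60
  expect_error(validate_model_inputs(bad), "52")

  bad <- inp
  bad$life_table$qx[nrow(bad$life_table)] <- 0.9
  expect_error(validate_model_inputs(bad), "terminal")
})

test_that("a probability outside [0,1] in the rate file is caught at load", {
  dir <- tempfile()
  write_model_inputs(fixture_inputs(), dir)
  r <- read.csv(file.path(dir, "rates.csv"))
  r$mean[r$arm == "intensive" & r$event == "stroke"] <- 1.2
  write.csv(r, file.path(dir, "rates.csv"), row.names = FALSE)
  expect_error(load_model_inputs(file.path(dir, "config.yaml")),
               "intensive, stroke")
})

test_that("missing optional cost entries default to zero with a warning", {
  dir <- tempfile()
  write_model_inputs(fixture_inputs(), dir)
  co <- read.csv(file.path(dir, "costs.csv"))
  co <- co[!(co$component == "acute_event" & co$name == "syncope"), ]
  write.csv(co, file.path(dir, "costs.csv"), row.names = FALSE)
  expect_warning(inp <- load_model_inputs(file.path(dir, "config.yaml")),
                 "syncope.*defaulting to 0")
  expect_identical(inp$costs$acute[["syncope"]], 0)
})

test_that("adherence presets carry the protocol fractions", {
  expect_equal(unlist(adherence_scenario("base")[2:3]),
               c(intensive = 0.70, standard = 0.75))
  expect_equal(unlist(adherence_scenario("worst")[2:3]),
               c(intensive = 0.00, standard = 1.00))
  expect_equal(unlist(adherence_scenario("best")[2:3]),
               c(intensive = 1.00, standard = 0.75))
  expect_error(adherence_scenario("custom", intensive = 1.2, standard = 0.5),
               "\\[0, 1\\]")
})

test_that("country profiles enforce threshold ordering and discount bounds", {
  uk <- country_profile("UK")
  expect_identical(uk$discount, 0.035)
  expect_identical(unname(uk$wtp), c(20000, 30000))
  expect_error(country_profile("CN", wtp = c(100, 50)), "lower WTP")
  expect_error(country_profile("US", discount = 0.5), "\\[0, 0.2\\]")
})
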