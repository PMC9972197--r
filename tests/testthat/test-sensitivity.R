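test_that("parameter draws are seed-reproducible and respect zero SDs", {
  inp <- fixture_inputs()
  d1 <- draw_parameters(inp, seed = 42, n = 5)
  d2 <- draw_parameters(inp, seed = 42, n = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1[[1]]$rates$mean, d1[[2]]$rates$mean))

  pinned <- inp
  pinned$rates$sd <- 0
  pinned$settings$cost_cv <- 0
  pinned$settings$utility_cv <- 0
  d <- draw_parameters(pinned, seed = 1, n = 3)
  for (k in 1:3) {
    expect_identical(d[[k]]$rates$mean, pinned$rates$mean)
    expect_identical(d[[k]]$costs, pinned$costs)
    expect_identical(d[[k]]$utilities, pinned$utilities)
  }
})

test_that("Beta moment matching recovers the target mean", {
  inp <- fixture_inputs()
  inp$rates$sd <- 0
  i <- which(inp$rates$arm == "standard" &
               inp$rates$event == "primary_composite")
  m <- 0.011683970; s <- 0.001644868
  inp$rates$sd[i] <- s
  draws <- vapply(draw_parameters(inp, seed = 9, n = 4000),
                  function(d) d$rates$mean[i], 0)
  expect_lt(abs(mean(draws) - m), 3 * s / sqrt(4000))
  expect_lt(abs(sd(draws) - s) / s, 0.1)
})

test_that("SDs incompatible with the Beta support fall back with a warning", {
  inp <- fixture_inputs()
  inp$rates$sd <- 0
  i <- which(inp$rates$arm == "intensive" & inp$rates$event == "syncope")
  inp$rates$sd[i] <- 0.4  # far beyond sqrt(m(1-m))
  expect_warning(d <- draw_parameters(inp, seed = 2, n = 10),
                 "clipped normal")
  v <- vapply(d, function(x) x$rates$mean[i], 0)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("a degenerate PSA collapses to a step function at the base ICER", {
  inp <- fixture_inputs()
  inp$rates$sd <- 0
  inp$settings$cost_cv <- 0
  inp$settings$utility_cv <- 0
  psa <- run_psa(inp, n = 5, seed = 1, horizon = 15)
  expect_identical(psa$n_failed, 0L)
  expect_lt(max(abs(psa$samples$delta_cost - psa$samples$delta_cost[1])), 1e-12)
  base_icer <- psa$samples$delta_cost[1] / psa$samples$delta_qaly[1]
  expect_true(all(psa$ceac$probability[psa$ceac$wtp > base_icer] == 1))
  expect_true(all(psa$ceac$probability[psa$ceac$wtp < base_icer] == 0))
})

test_that("a dominant configuration puts every draw in the southeast quadrant", {
  inp <- fixture_inputs()
  inp$rates$sd <- 0
  inp$settings$cost_cv <- 0
  inp$settings$utility_cv <- 0
  # intensive treatment made free: fewer events, lower cost in every draw
  inp$costs$intervention[["intensive"]] <- 0
  psa <- run_psa(inp, n = 4, seed = 8, horizon = 15)
  expect_true(all(psa$samples$delta_qaly > 0))
  expect_true(all(psa$samples$delta_cost < 0))
  expect_identical(unname(psa$quadrants[c("NE", "NW", "SW")]), rep(0L, 3))
  expect_true(all(psa$ceac$probability == 1))
})

test_that("PSA means agree with the base case within Monte Carlo error", {
  inp <- fixture_inputs()
  base <- run_cea(inp)$result
  psa <- run_psa(inp, n = 200, seed = 5)
  se_c <- sd(psa$samples$delta_cost) / sqrt(nrow(psa$samples))
  se_e <- sd(psa$samples$delta_qaly) / sqrt(nrow(psa$samples))
  expect_lt(abs(mean(psa$samples$delta_cost) - base$delta_cost), 3 * se_c)
  expect_lt(abs(mean(psa$samples$delta_qaly) - base$delta_qaly), 3 * se_e)
  expect_identical(sum(psa$quadrants) + psa$n_failed, 200L)
  # acceptability at the lower threshold: intensive control is the likely
  # cost-effective strategy on the base-case fixture
  expect_gte(ceac_at(psa, psa$wtp[["lower"]]), 0.5)
})

test_that("the tornado ranks treatment cost among the top drivers", {
  tor <- one_way_tornado(fixture_inputs())
  expect_true(all(diff(tor$width) <= 1e-9))
  expect_lte(which(tor$parameter == "cost:intervention:intensive"), 3)
  # an inert parameter has a zero-width interval
  expect_identical(tor$width[tor$parameter == "utility:event:cv_death"], 0)
  # raising the intensive treatment cost raises the ICER
  row <- tor[tor$parameter == "cost:intervention:intensive", ]
  expect_gt(row$icer_high, attr(tor, "base_icer"))
  expect_lt(row$icer_low, attr(tor, "base_icer"))
  # continuity: intervals bracket the base-case ICER
  for (p in c("rate:standard:stroke", "cost:background",
              "utility:state:post_stroke")) {
    row <- tor[tor$parameter == p, ]
    expect_lte(min(row$icer_low, row$icer_high) - 1e-9, attr(tor, "base_icer"))
    expect_gte(max(row$icer_low, row$icer_high) + 1e-9, attr(tor, "base_icer"))
  }
})

test_that("unknown parameter ids are rejected by name", {
  expect_error(perturb_parameter(fixture_inputs(), "rate:standard:nonsense", 1.1),
               "rate:standard:nonsense")
})
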