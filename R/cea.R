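#' Fit the cohort cost-effectiveness model
#'
#' The package's central entry point: runs the deterministic Markov cohort
#' for both treatment arms over the requested horizon and summarises
#' incremental cost-effectiveness. Returns a classed object with
#' `print()`, `summary()`, `plot()` and `simulate()` (probabilistic
#' sensitivity analysis) methods.
#'
#' @param inputs A [model_inputs()] bundle, e.g. from [generate_inputs()]
#'   or [load_model_inputs()].
#' @param horizon `"lifetime"` or a whole number of years.
#' @param cohort_size Cohort size for reported counts (default from
#'   `inputs$settings`).
#' @return A list of class `cea` with elements `inputs`, `traces`
#'   (per-arm `cohort_trace`), `result` (a `ce_result`) and `horizon`.
#' @examples
#' fit <- run_cea(generate_inputs(synthetic_profile("CN", seed = 1)))
#' fit
#' summary(fit)
#' @export
run_cea <- function(inputs, horizon = "lifetime", cohort_size = NULL) {
  traces <- lapply(stats::setNames(.ARMS, .ARMS), function(a) {
    run_cohort(inputs, a, horizon = horizon, cohort_size = cohort_size)
  })
  structure(list(
    inputs = inputs,
    traces = traces,
    result = compute_ce(traces$intensive, traces$standard, inputs$country),
    horizon = horizon), class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Markov cohort CE model: intensive vs standard BP control, %s, horizon %s\n",
              x$inputs$country$country,
              if (identical(x$horizon, "lifetime")) "lifetime"
              else paste(x$horizon, "years")))
  print(x$result)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  v <- vapply(object$traces, function(tr) {
    c(incidence_4y = if (nrow(tr) >= attr(tr, "trial_years")) {
        incidence_per_100py(tr, window = attr(tr, "trial_years"))
      } else NA_real_,
      life_years = sum(rowSums(as.data.frame(tr)[, paste0("occ_", .ALIVE)])),
      qaly = sum(tr$qaly_disc), cost = sum(tr$cost_disc))
  }, numeric(4))
  out <- list(cea = object, arm_summary = v)
  class(out) <- "summary.cea"
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  print(x$cea)
  v <- x$arm_summary
  cat("\nPer-arm detail:\n")
  cat(sprintf("  trial-period primary-event incidence: %.2f vs %.2f per 100 person-years\n",
              v["incidence_4y", "intensive"], v["incidence_4y", "standard"]))
  cat(sprintf("  undiscounted life-years: %.2f vs %.2f\n",
              v["life_years", "intensive"], v["life_years", "standard"]))
  invisible(x)
}

#' Plot a fitted cohort model
#'
#' `type = "occupancy"` draws the state-occupancy trace for one arm;
#' `type = "incidence"` overlays the two arms' cumulative primary-event
#' incidence curves (the trial-validation visual).
#'
#' @param x A `cea` object.
#' @param type Plot type.
#' @param arm Arm for the occupancy plot.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cea <- function(x, type = c("occupancy", "incidence"),
                     arm = "intensive", ...) {
  type <- match.arg(type)
  if (type == "occupancy") {
    tr <- as.data.frame(x$traces[[arm]])
    occ <- as.matrix(tr[, paste0("occ_", .STATES)])
    graphics::matplot(tr$age, occ, type = "l", lty = 1,
                      col = grDevices::hcl.colors(7, "Dark 3"),
                      xlab = "Age (years)", ylab = "Occupancy fraction",
                      main = sprintf("State occupancy (%s arm)", arm), ...)
    graphics::legend("right", legend = .STATES, lty = 1, cex = 0.7,
                     col = grDevices::hcl.colors(7, "Dark 3"))
  } else {
    ci <- lapply(x$traces, cumulative_incidence_curve)
    graphics::plot(x$traces$intensive$age, ci$intensive, type = "s",
                   col = "firebrick", xlab = "Age (years)",
                   ylab = "Cumulative primary-event incidence",
                   main = "Cumulative incidence by arm",
                   ylim = range(0, unlist(ci)), ...)
    graphics::lines(x$traces$standard$age, ci$standard, type = "s",
                    col = "navy")
    graphics::legend("topleft", legend = c("intensive", "standard"),
                     col = c("firebrick", "navy"), lty = 1)
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis as `simulate()`
#'
#' Monte Carlo draws of all model inputs from their uncertainty
#' distributions, one full two-arm model run per draw. Equivalent to
#' [run_psa()] on the fitted model's inputs.
#'
#' @param object A `cea` object.
#' @param nsim Number of draws.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Passed to [run_psa()].
#' @return A `psa_result`.
#' @export
simulate.cea <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$inputs, n = nsim, seed = seed,
          horizon = object$horizon, ...)
}
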