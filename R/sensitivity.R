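# One-way (tornado) and probabilistic sensitivity analysis.

# --- scalar-parameter registry ---------------------------------------------

#' Enumerate the scalar parameters of a model-input bundle
#'
#' Parameter ids take the form `rate:<arm>:<event>`,
#' `cost:intervention:<arm>`, `cost:acute:<event>`,
#' `cost:chronic:<state>`, `cost:background`, `utility:baseline`,
#' `utility:age_decrement`, `utility:state:<state>`,
#' `utility:event:<event>`.
#'
#' @param inputs A [model_inputs()] bundle.
#' @return Data frame `id`, `value`.
#' @export
list_scalar_parameters <- function(inputs) {
  r <- inputs$rates
  ids <- c(sprintf("rate:%s:%s", r$arm, r$event),
           sprintf("cost:intervention:%s", names(inputs$costs$intervention)),
           sprintf("cost:acute:%s", names(inputs$costs$acute)),
           sprintf("cost:chronic:%s", names(inputs$costs$chronic)),
           "cost:background",
           "utility:baseline", "utility:age_decrement",
           sprintf("utility:state:%s", .CHRONIC),
           sprintf("utility:event:%s", names(inputs$utilities$event_decrement)))
  vals <- c(r$mean, inputs$costs$intervention, inputs$costs$acute,
            inputs$costs$chronic, inputs$costs$background,
            inputs$utilities$baseline, inputs$utilities$age_decrement,
            inputs$utilities$state_decrement[.CHRONIC],
            inputs$utilities$event_decrement)
  data.frame(id = ids, value = unname(vals), stringsAsFactors = FALSE)
}

#' Multiply one scalar parameter by a factor
#'
#' Returns a modified deep copy; probabilities and utilities are capped
#' at 1. Unknown ids are an error naming the id.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param id Parameter id (see [list_scalar_parameters()]).
#' @param factor Multiplicative factor.
#' @return A modified `model_inputs` bundle.
#' @export
perturb_parameter <- function(inputs, id, factor) {
  p <- strsplit(id, ":", fixed = TRUE)[[1]]
  cap1 <- function(x) pmin(x, 1)
  if (p[1] == "rate") {
    hit <- inputs$rates$arm == p[2] & inputs$rates$event == p[3]
    if (!any(hit)) .fail("unknown parameter id '", id, "'")
    inputs$rates$mean[hit] <- cap1(inputs$rates$mean[hit] * factor)
  } else if (p[1] == "cost") {
    if (p[2] == "intervention") {
      inputs$costs$intervention[[p[3]]] <- inputs$costs$intervention[[p[3]]] * factor
    } else if (p[2] == "acute") {
      inputs$costs$acute[[p[3]]] <- inputs$costs$acute[[p[3]]] * factor
    } else if (p[2] == "chronic") {
      inputs$costs$chronic[[p[3]]] <- inputs$costs$chronic[[p[3]]] * factor
    } else if (p[2] == "background") {
      inputs$costs$background <- inputs$costs$background * factor
    } else .fail("unknown parameter id '", id, "'")
  } else if (p[1] == "utility") {
    if (p[2] == "baseline") {
      inputs$utilities$baseline <- cap1(inputs$utilities$baseline * factor)
    } else if (p[2] == "age_decrement") {
      inputs$utilities$age_decrement <- cap1(inputs$utilities$age_decrement * factor)
    } else if (p[2] == "state") {
      inputs$utilities$state_decrement[[p[3]]] <-
        cap1(inputs$utilities$state_decrement[[p[3]]] * factor)
    } else if (p[2] == "event") {
      inputs$utilities$event_decrement[[p[3]]] <-
        cap1(inputs$utilities$event_decrement[[p[3]]] * factor)
    } else .fail("unknown parameter id '", id, "'")
  } else .fail("unknown parameter id '", id, "'")
  inputs
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model with each scalar parameter at `1 - fraction`
#' and `1 + fraction` times its base value (all else fixed) and records
#' the resulting ICERs, ranked by interval width. Perturbations that
#' produce invalid inputs are skipped with a warning.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param fraction Relative perturbation (default 0.10).
#' @param horizon Passed to [run_cea()].
#' @return Data frame of class `tornado`: `parameter`, `base_value`,
#'   `icer_low`, `icer_high`, `width`, sorted by decreasing width; the
#'   base-case ICER is attached as attribute `base_icer`.
#' @export
one_way_tornado <- function(inputs, fraction = 0.10, horizon = "lifetime") {
  base <- run_cea(inputs, horizon = horizon)$result$icer
  pars <- list_scalar_parameters(inputs)
  res <- lapply(seq_len(nrow(pars)), function(i) {
    ic <- vapply(c(1 - fraction, 1 + fraction), function(f) {
      tryCatch(
        run_cea(perturb_parameter(inputs, pars$id[i], f),
                horizon = horizon)$result$icer,
        error = function(e) {
          warning("skipping ", pars$id[i], ": ", conditionMessage(e),
                  call. = FALSE)
          NA_real_
        })
    }, 0)
    data.frame(parameter = pars$id[i], base_value = pars$value[i],
               icer_low = ic[1], icer_high = ic[2],
               width = abs(ic[2] - ic[1]))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"), base_icer = base,
            fraction = fraction)
}

#' @export
print.tornado <- function(x, n = 10, ...) {
  cat(sprintf("<tornado> +/-%.0f%% one-way sensitivity, base ICER %.0f\n",
              100 * attr(x, "fraction"), attr(x, "base_icer")))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' @export
plot.tornado <- function(x, n = 10, ...) {
  d <- utils::head(x[nrow(x):1, ], n)
  base <- attr(x, "base_icer")
  graphics::plot(NULL, xlim = range(c(d$icer_low, d$icer_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER", ylab = "", main = "One-way sensitivity")
  graphics::segments(d$icer_low, seq_len(nrow(d)), d$icer_high,
                     seq_len(nrow(d)), lwd = 6, col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}

# --- probabilistic sensitivity analysis -------------------------------------

.beta_params <- function(m, s) {
  v <- s^2
  k <- m * (1 - m) / v - 1
  c(alpha = m * k, beta = (1 - m) * k)
}

# one sampler per parameter; falls back to a clipped normal when the SD
# is incompatible with the Beta support
.sample_prob <- function(n, m, s) {
  if (s == 0 || m == 0 || m == 1) return(rep(m, n))
  if (s^2 >= m * (1 - m)) {
    warning(sprintf(
      "SD %.3g incompatible with Beta support for mean %.3g; using clipped normal",
      s, m), call. = FALSE)
    return(pmin(pmax(stats::rnorm(n, m, s), 0), 1))
  }
  p <- .beta_params(m, s)
  stats::rbeta(n, p[["alpha"]], p[["beta"]])
}

.sample_lognormal <- function(n, m, s) {
  if (s == 0 || m == 0) return(rep(m, n))
  sdlog2 <- log(1 + s^2 / m^2)
  stats::rlnorm(n, log(m) - sdlog2 / 2, sqrt(sdlog2))
}

.sample_cost <- function(n, m, s) {
  if (s == 0 || m == 0) return(rep(m, n))
  stats::rgamma(n, shape = m^2 / s^2, rate = m / s^2)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Event probabilities are drawn from moment-matched Beta distributions
#' using the rate table's means and SDs (log-normal where the table says
#' so); costs from moment-matched Gammas with coefficient of variation
#' `settings$cost_cv`; utilities and decrements from moment-matched Betas
#' with coefficient of variation `settings$utility_cv`. Draws are
#' independent across parameters; identical `(seed, n)` give identical
#' draws. A SD of 0 pins the parameter at its mean.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param seed Integer seed.
#' @param n Number of draws (>= 1).
#' @return List of `n` modified `model_inputs` bundles.
#' @export
draw_parameters <- function(inputs, seed = 1, n = 1) {
  if (n < 1) .fail("`n` must be >= 1")
  set.seed(seed)
  s <- inputs$settings
  r <- inputs$rates
  rate_draws <- matrix(0, n, nrow(r))
  for (i in seq_len(nrow(r))) {
    rate_draws[, i] <- if (r$distribution[i] == "log_normal") {
      pmin(.sample_lognormal(n, r$mean[i], r$sd[i]), 1)
    } else {
      .sample_prob(n, r$mean[i], r$sd[i])
    }
  }
  draw_named <- function(x, f, cv) {
    m <- matrix(0, n, length(x), dimnames = list(NULL, names(x)))
    for (j in seq_along(x)) m[, j] <- f(n, x[[j]], cv * x[[j]])
    m
  }
  co <- inputs$costs
  int_d <- draw_named(co$intervention, .sample_cost, s$cost_cv)
  acu_d <- draw_named(co$acute, .sample_cost, s$cost_cv)
  chr_d <- draw_named(co$chronic, .sample_cost, s$cost_cv)
  bg_d <- .sample_cost(n, co$background, s$cost_cv * co$background)
  u <- inputs$utilities
  base_d <- .sample_prob(n, u$baseline, s$utility_cv * u$baseline)
  aged_d <- .sample_prob(n, u$age_decrement, s$utility_cv * u$age_decrement)
  st_d <- draw_named(u$state_decrement, .sample_prob, s$utility_cv)
  ev_d <- draw_named(u$event_decrement, .sample_prob, s$utility_cv)

  lapply(seq_len(n), function(k) {
    x <- inputs
    x$rates$mean <- rate_draws[k, ]
    x$costs$intervention[] <- int_d[k, ]
    x$costs$acute[] <- acu_d[k, ]
    x$costs$chronic[] <- chr_d[k, ]
    x$costs$background <- bg_d[k]
    x$utilities$baseline <- base_d[k]
    x$utilities$age_decrement <- aged_d[k]
    x$utilities$state_decrement[] <- st_d[k, ]
    x$utilities$event_decrement[] <- ev_d[k, ]
    x
  })
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full two-arm model once per Monte Carlo parameter draw and
#' summarises the joint uncertainty: per-draw incremental costs and
#' QALYs, net monetary benefit, the cost-effectiveness acceptability
#' curve (fraction of draws with positive NMB across a willingness-to-pay
#' grid), and cost-effectiveness-plane quadrant tallies. Draws whose
#' inputs fail validation are excluded and counted, not resampled, so the
#' draw stream stays reproducible.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param n Number of draws (>= 2); the study convention is 1000.
#' @param seed Integer seed.
#' @param horizon Passed to [run_cohort()].
#' @param wtp_grid Optional willingness-to-pay grid; default 101 evenly
#'   spaced points from 0 to 1.5x the upper threshold plus the two exact
#'   thresholds.
#' @param keep_draws If `TRUE`, attach the matrix of sampled scalar
#'   parameter values (one row per draw, columns per
#'   [list_scalar_parameters()]) as element `param_draws`.
#' @return A list of class `psa_result`: `samples` (data frame with
#'   `draw`, `delta_cost`, `delta_qaly`, `nmb_lower`, `nmb_upper`),
#'   `ceac` (data frame `wtp`, `probability`), `quadrants` (NE/SE/NW/SW
#'   tallies), `n_failed`, `prob_ce` (probability cost-effective at the
#'   two thresholds), and the base-case increments.
#' @export
run_psa <- function(inputs, n = 1000, seed = 1, horizon = "lifetime",
                    wtp_grid = NULL, keep_draws = FALSE) {
  if (n < 2) .fail("`n` must be >= 2")
  draws <- draw_parameters(inputs, seed = seed, n = n)
  param_draws <- if (keep_draws) {
    ids <- list_scalar_parameters(inputs)$id
    t(vapply(draws, function(d) list_scalar_parameters(d)$value,
             numeric(length(ids)))) |>
      `colnames<-`(ids)
  }
  dc <- de <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    ok <- tryCatch({
      x <- validate_model_inputs(draws[[k]])
      ti <- run_cohort(x, "intensive", horizon = horizon)
      ts <- run_cohort(x, "standard", horizon = horizon)
      dc[k] <- sum(ti$cost_disc) - sum(ts$cost_disc)
      de[k] <- sum(ti$qaly_disc) - sum(ts$qaly_disc)
      TRUE
    }, error = function(e) FALSE)
  }
  keep <- is.finite(dc) & is.finite(de)
  wtp <- inputs$country$wtp
  if (is.null(wtp_grid)) {
    wtp_grid <- sort(unique(c(seq(0, 1.5 * wtp[["upper"]], length.out = 101),
                              wtp)))
  }
  ceac <- vapply(wtp_grid, function(l) mean(l * de[keep] - dc[keep] > 0), 0)
  quad <- c(NE = sum(de[keep] > 0 & dc[keep] >= 0),
            SE = sum(de[keep] > 0 & dc[keep] < 0),
            NW = sum(de[keep] <= 0 & dc[keep] >= 0),
            SW = sum(de[keep] <= 0 & dc[keep] < 0))
  samples <- data.frame(draw = which(keep), delta_cost = dc[keep],
                        delta_qaly = de[keep],
                        nmb_lower = wtp[["lower"]] * de[keep] - dc[keep],
                        nmb_upper = wtp[["upper"]] * de[keep] - dc[keep])
  structure(list(
    samples = samples,
    ceac = data.frame(wtp = wtp_grid, probability = ceac),
    quadrants = quad, n = n, n_failed = sum(!keep), seed = seed,
    wtp = wtp,
    prob_ce = c(lower = mean(samples$nmb_lower > 0),
                upper = mean(samples$nmb_upper > 0)),
    param_draws = param_draws,
    country = inputs$country), class = "psa_result")
}

#' Probability of cost-effectiveness at given thresholds
#'
#' Fraction of retained PSA draws with positive net monetary benefit at
#' each willingness-to-pay value (the acceptability-curve ordinate).
#'
#' @param psa A `psa_result`.
#' @param wtp Numeric vector of willingness-to-pay thresholds.
#' @return Numeric vector in \eqn{[0, 1]}.
#' @export
ceac_at <- function(psa, wtp) {
  vapply(wtp, function(l) {
    mean(l * psa$samples$delta_qaly - psa$samples$delta_cost > 0)
  }, 0)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%d failed), %s\n", x$n, x$n_failed,
              x$country$country))
  cat(sprintf("  mean increments: dC %.0f, dE %.4f\n",
              mean(x$samples$delta_cost), mean(x$samples$delta_qaly)))
  cat(sprintf("  P(cost-effective) at WTP %s / %s: %.1f%% / %.1f%%\n",
              format(x$wtp[["lower"]], big.mark = ","),
              format(x$wtp[["upper"]], big.mark = ","),
              100 * x$prob_ce[["lower"]], 100 * x$prob_ce[["upper"]]))
  cat(sprintf("  CE-plane quadrants NE/SE/NW/SW: %d/%d/%d/%d\n",
              x$quadrants[["NE"]], x$quadrants[["SE"]],
              x$quadrants[["NW"]], x$quadrants[["SW"]]))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    graphics::plot(x$samples$delta_qaly, x$samples$delta_cost, pch = 16,
                   cex = 0.5, col = grDevices::adjustcolor("navy", 0.4),
                   xlab = "Incremental QALYs", ylab = "Incremental cost",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(0, x$wtp[["lower"]], lty = 2)
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "l", lwd = 2,
                   ylim = c(0, 1), xlab = "Willingness to pay per QALY",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(v = x$wtp, lty = 3)
  }
  invisible(x)
}

#' Serialize PSA outputs to CSV
#'
#' Writes `samples.csv` (one row per retained draw) and `ceac.csv`
#' (willingness-to-pay grid and probability).
#'
#' @param x A `psa_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_psa <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(x$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  invisible(dir)
}
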