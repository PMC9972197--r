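# Independent oracle: per-individual stochastic microsimulation using the
# same per-cycle probabilities as the deterministic engine, but advancing
# every individual with its own uniform draws. Used to cross-check the
# engine's expectation propagation.

microsim_occupancy <- function(inputs, arm, n_ind, n_years, seed) {
  set.seed(seed)
  states <- health_states()
  cvn <- cv_events()
  nonfatal <- cvn[cvn != "cv_death"]
  dest <- event_destination()
  state <- rep(1L, n_ind)
  for (k in seq_len(n_years)) {
    age <- inputs$settings$start_age + k - 1L
    phase <- if (k <= inputs$settings$trial_years) "trial" else "post_trial"
    ps <- lapply(states[1:5], function(s) {
      cycle_probabilities(s, age, arm, inputs, phase)
    })
    u1 <- stats::runif(n_ind)
    u2 <- stats::runif(n_ind)
    u3 <- stats::runif(n_ind)
    new <- state
    for (si in 1:5) {
      idx <- which(state == si)
      if (!length(idx)) next
      p <- ps[[si]]
      cvd <- u1[idx] < p$cv[["cv_death"]]
      ncv <- !cvd & u2[idx] < p$noncv_death
      ev <- findInterval(u3[idx], cumsum(c(0, p$cv[nonfatal]))) # 6 = none
      ns <- rep(si, length(idx))
      hit <- !cvd & !ncv & ev <= 5
      ns[hit] <- match(dest[nonfatal[ev[hit]]], states)
      ns[cvd] <- 6L
      ns[ncv] <- 7L
      new[idx] <- ns
    }
    state <- new
  }
  tabulate(state, nbins = 7L) / n_ind
}
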