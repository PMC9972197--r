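#' Trial-period yearly transition probabilities
#'
#' Yearly probabilities of cardiovascular events, treatment-related adverse
#' events, cardiovascular death and all-cause death observed over the
#' 4-year STEP trial (intensive 110-130 mm Hg vs standard 130-150 mm Hg
#' systolic targets, patients aged 60-80). Means and SDs parameterise the
#' per-cycle transitions during the trial phase and the Beta sampling
#' distributions of the probabilistic sensitivity analysis.
#'
#' @return A data frame with columns `event`, `arm`, `mean`, `sd`,
#'   `distribution` (26 rows: 13 event types for each arm).
#' @seealso [step_relative_risk()] for the primary-outcome relative risk.
#' @examples
#' r <- step_event_rates()
#' subset(r, event == "primary_composite")
#' @export
step_event_rates <- function() {
  tab <- rbind(
    c("primary_composite", 0.008776182, 0.001431865, 0.011683970, 0.001644868),
    c("stroke",            0.002840265, 0.000817006, 0.004185055, 0.000988161),
    c("acs",               0.003256504, 0.000874643, 0.004838185, 0.001062126),
    c("acute_hf",          0.000299955, 0.000265844, 0.000899595, 0.000458898),
    c("revascularization", 0.000999500, 0.000485107, 0.001998001, 0.000683520),
    c("af",                0.001417103, 0.000577506, 0.001467614, 0.000585969),
    c("cv_death",          0.001062262, 0.000500090, 0.001467614, 0.000585969),
    c("hypotension",       0.008715688, 0.001426965, 0.006685776, 0.001247404),
    c("dizziness",         0.002662037, 0.000791028, 0.002882637, 0.000820646),
    c("syncope",           0.000353711, 0.000288676, 0.000117171, 0.000165681),
    c("fracture",          0.000884983, 0.000456498, 0.001114796, 0.000510791),
    c("aki",               0.003386435, 0.000909393, 0.003724914, 0.000949418),
    c("all_cause_death",   0.003971272, 0.000965527, 0.003770095, 0.000938088)
  )
  data.frame(
    event = rep(tab[, 1], 2L),
    arm = rep(.ARMS, each = nrow(tab)),
    mean = as.numeric(c(tab[, 2], tab[, 4])),
    sd = as.numeric(c(tab[, 3], tab[, 5])),
    distribution = "beta",
    stringsAsFactors = FALSE
  )
}

#' Primary-outcome relative risk (intensive vs standard)
#'
#' @return List with `mean`, `sd` and `distribution` ("log_normal").
#' @export
step_relative_risk <- function() {
  list(mean = 0.751130175, sd = 0.215494892, distribution = "log_normal")
}
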