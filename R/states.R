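# State and event vocabularies shared by every module.

.STATES <- c("no_cvd", "chronic_chd", "post_stroke", "chronic_hf",
             "chronic_af", "dead_cv", "dead_noncv")
.ALIVE  <- .STATES[1:5]
.CHRONIC <- .STATES[2:5]

# six cardiovascular event types (the trial's primary composite)
.CV_EVENTS <- c("stroke", "acs", "acute_hf", "revascularization", "af",
                "cv_death")
# nonfatal CV events and where they send the cohort fraction
.CV_NONFATAL <- .CV_EVENTS[1:5]
.CV_DEST <- c(stroke = "post_stroke", acs = "chronic_chd",
              acute_hf = "chronic_hf", revascularization = "chronic_chd",
              af = "chronic_af")
# treatment-related adverse events (state preserving; cost/utility only)
.AE_EVENTS <- c("hypotension", "dizziness", "syncope", "fracture", "aki")
# rows required of an event-rate table (per arm)
.RATE_EVENTS <- c("primary_composite", .CV_EVENTS, .AE_EVENTS,
                  "all_cause_death")
.ARMS <- c("intensive", "standard")

#' Model vocabularies
#'
#' The seven health-state labels (six clinical states with death split by
#' cause so cardiovascular and non-cardiovascular deaths can be tallied
#' separately), the two treatment arms, and the event types tracked by the
#' cohort engine.
#'
#' @return Character vectors of labels.
#' @examples
#' health_states()
#' cv_events()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
health_states <- function() .STATES

#' @rdname vocabularies
#' @export
arms <- function() .ARMS

#' @rdname vocabularies
#' @export
cv_events <- function() .CV_EVENTS

#' @rdname vocabularies
#' @export
adverse_events <- function() .AE_EVENTS

#' @rdname vocabularies
#' @export
rate_events <- function() .RATE_EVENTS

#' @rdname vocabularies
#' @export
event_destination <- function() .CV_DEST
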