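#' Probability / rate calculus for yearly cycle models
#'
#' Under a constant-hazard (exponential) assumption, a probability \eqn{p}
#' observed over \eqn{t} years corresponds to the event rate
#' \eqn{r = -\ln(1 - p) / t}, and a rate maps back to a probability as
#' \eqn{p = 1 - e^{-rt}}. These two transforms are the basis for changing
#' cycle lengths, blending treatment arms in rate space and subtracting
#' competing causes of death.
#'
#' @param p Probability in \eqn{[0, 1)}; vectorised.
#' @param r Nonnegative rate per year; vectorised.
#' @param t Duration in years (> 0).
#' @return `prob_to_rate()`: rate per year; `rate_to_prob()`: probability in
#'   \eqn{[0, 1)}. The two are mutual inverses for matching `t`.
#' @examples
#' prob_to_rate(0.5)              # log(2)
#' rate_to_prob(log(2))           # 0.5
#' rescale_probability(0.10, 10, 1)
#' @name rate_transforms
NULL

#' @rdname rate_transforms
#' @export
prob_to_rate <- function(p, t = 1) {
  .assert_num(p, "p")
  .assert_num(t, "t")
  if (any(p < 0) || any(p >= 1)) .fail("`p` must lie in [0, 1)")
  if (any(t <= 0)) .fail("`t` must be positive")
  -log1p(-p) / t
}

#' @rdname rate_transforms
#' @export
rate_to_prob <- function(r, t = 1) {
  .assert_num(r, "r")
  .assert_num(t, "t")
  if (any(r < 0)) .fail("`r` must be nonnegative")
  if (any(t <= 0)) .fail("`t` must be positive")
  -expm1(-r * t)
}

#' Rescale a probability to a different duration
#'
#' Composition of [prob_to_rate()] and [rate_to_prob()]: converts a
#' probability over `from_t` years into the equivalent constant-hazard
#' probability over `to_t` years. Identity when the durations match.
#'
#' @inheritParams rate_transforms
#' @param from_t,to_t Source and target durations in years (> 0).
#' @return Probability over `to_t` years.
#' @export
rescale_probability <- function(p, from_t, to_t) {
  rate_to_prob(prob_to_rate(p, from_t), to_t)
}
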