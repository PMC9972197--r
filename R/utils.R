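`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial rounding used when reporting ICERs in whole currency units
#' (base \code{round()} rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(-0.5)  # -1
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop without the call in the message
.fail <- function(...) stop(..., call. = FALSE)

.assert_num <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    .fail(sprintf("`%s` must be finite numeric", name))
  }
  invisible(x)
}
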