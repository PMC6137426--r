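#' Wrap angles onto the signed half-circle
#'
#' Maps angles in degrees onto `(-180, 180]`, the convention used for every
#' signed circular difference in the package (0 deg = rightward,
#' counter-clockwise positive). The boundary case maps to +180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, in `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -190, 360, 180, 540))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  y <- x %% 360
  i <- which(y > 180)
  y[i] <- y[i] - 360
  y
}

#' Signed circular report error
#'
#' The signed difference `reported - true`, wrapped to `(-180, 180]`. This is
#' the error delta that enters the transformed-performance statistic.
#'
#' @param reported,true Numeric vectors of directions in degrees.
#' @return Signed error in degrees, in `(-180, 180]`.
#' @examples
#' circular_error(350, 10)  # -20
#' circular_error(10, 190)  # boundary maps to +180
#' @export
circular_error <- function(reported, true) {
  if (!all(is.finite(reported)) || !all(is.finite(true))) {
    abort("`reported` and `true` must be finite.")
  }
  wrap_angle(reported - true)
}

#' Circular separation between two directions
#'
#' Unsigned angular distance in `[0, 180]` degrees.
#'
#' @param a,b Numeric vectors of directions in degrees.
#' @return Numeric vector of separations in degrees.
#' @export
circular_separation <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Transformed performance
#'
#' Maps an angular report error delta (degrees) to the probability-like score
#' `TP = 1 - |delta| / 180`: 1 for a perfect report, 0.5 at chance (uniform
#' guessing), 0 for the maximal 180-degree error. Inputs must already be
#' wrapped; use [circular_error()] first.
#'
#' @param delta Signed angular errors in degrees, `|delta| <= 180`.
#' @return Numeric vector of TP scores in `[0, 1]`.
#' @examples
#' tp(c(0, -90, 180))
#' @export
tp <- function(delta) {
  if (!all(is.finite(delta))) abort("`delta` must be finite.")
  if (any(abs(delta) > 180 + 1e-9)) {
    abort("|delta| must be <= 180; wrap errors with `circular_error()` first.")
  }
  1 - pmin(abs(delta), 180) / 180
}

# wrapped-Gaussian angular noise, degrees
rwrapped <- function(n, sd) {
  wrap_angle(rnorm(n, 0, sd))
}
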