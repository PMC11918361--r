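# Shared helpers: angle/hour wrapping, unit conversion, skew-normal sampling.

HOURS_PER_CYCLE <- 24

#' Wrap phase values in hours into (-12, 12]
#'
#' Phases are relative statistics on a 24-hour circle; the convention
#' throughout the package is that a pixel or neuron is at most 12 hours
#' advanced or 12 hours delayed relative to the reference oscillation.
#'
#' @param h numeric vector of hours.
#' @return values wrapped into `(-12, 12]`.
#' @examples
#' wrap_hours(c(13, -13, 22, 12, -12))
#' @export
wrap_hours <- function(h) {
  w <- h %% HOURS_PER_CYCLE
  ifelse(w > HOURS_PER_CYCLE / 2, w - HOURS_PER_CYCLE, w)
}

#' Wrap angles in radians into (-pi, pi]
#'
#' Principal value of the argument of `exp(1i * theta)`.
#'
#' @param theta numeric vector of radians.
#' @return values wrapped into `(-pi, pi]`.
#' @export
wrap_radians <- function(theta) {
  w <- theta %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Convert between hours and radians on the 24-hour circle
#'
#' @param h,theta numeric vectors.
#' @return the converted vector (`hours_to_radians`: radians;
#'   `radians_to_hours`: hours).
#' @export
hours_to_radians <- function(h) h * 2 * pi / HOURS_PER_CYCLE

#' @rdname hours_to_radians
#' @export
radians_to_hours <- function(theta) theta * HOURS_PER_CYCLE / (2 * pi)

# Skew-normal deviates by the additive representation:
# z = delta |u0| + sqrt(1 - delta^2) v with u0, v iid standard normal.
# shape = 0 recovers the normal distribution.
rskewnorm <- function(n, location = 0, scale = 1, shape = 0) {
  stopifnot(scale >= 0)
  delta <- shape / sqrt(1 + shape^2)
  u0 <- rnorm(n)
  v <- rnorm(n)
  location + scale * (delta * abs(u0) + sqrt(1 - delta^2) * v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scn <- function(..., class) {
  stop(structure(
    class = c(class, "scn_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
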