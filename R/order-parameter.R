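# The Kuramoto order parameter and the calibration of the snapshot scale
# constant.

#' Kuramoto order parameter
#'
#' The modulus of the mean unit phasor of a phase population,
#' \deqn{O(\{\phi_j\}) = \left| \frac{1}{N} \sum_j e^{i\phi_j} \right|,}
#' equal to 1 when all phases are identical and near 0 when phases are
#' uniformly scattered on the circle. Invariant under global rotation and
#' permutation of the phases.
#'
#' @param phases numeric vector of phases.
#' @param units `"radians"` (default) or `"hours"` (converted via
#'   `2 pi / 24`).
#' @return a number in `[0, 1]`.
#' @examples
#' order_parameter(rep(1.3, 100))        # 1: complete synchrony
#' order_parameter(c(0, pi))             # 0: antipodal cancellation
#' @export
order_parameter <- function(phases, units = c("radians", "hours")) {
  units <- match.arg(units)
  if (length(phases) == 0)
    stop_scn("empty phase collection", class = "scn_config_error")
  th <- if (units == "hours") hours_to_radians(phases) else phases
  Mod(mean(exp(1i * th)))
}

#' Calibrate the snapshot scale constant by synchronization
#'
#' The snapshot model assigns phases \eqn{\phi_i = \alpha m_i} to
#' mean-centered brightness values \eqn{m_i}. The single parameter
#' \eqn{\alpha} sets the dispersion of the estimated phases; it is tuned so
#' that their order parameter equals a representative target (default 0.8,
#' the synchronization level of slice tissue at CT1900). Since
#' \eqn{O(0) = 1} and O decreases as \eqn{\alpha} grows, the smallest
#' positive solution on this initial decreasing branch is returned (found by
#' bracketing plus root refinement); if the branch turns upward before
#' reaching the target, calibration fails rather than jumping to a larger
#' branch.
#'
#' @param intensities per-neuron brightness values; they are mean-centered
#'   internally.
#' @param target target order parameter, in (0, 1) (default 0.8).
#' @param tol solver tolerance on alpha (achieved order parameter is within
#'   1e-6 of the target).
#' @return an object of class `scn_calibration`: `alpha_cal` (radians per
#'   mean-centered intensity unit), `target`, `achieved`, `n`, and a
#'   fingerprint of the centered intensities used to guard against
#'   scale/table mismatches downstream.
#' @examples
#' # Two-point intensities {-1, +1}: O(alpha) = |cos(alpha)|, so the
#' # calibrated alpha is acos(0.8).
#' calibrate_alpha(c(-1, 1), target = 0.8)$alpha_cal
#' acos(0.8)
#' @export
calibrate_alpha <- function(intensities, target = 0.8, tol = 1e-9) {
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target >= 1)
    stop_scn("target order parameter must lie strictly between 0 and 1",
             class = "scn_config_error")
  m <- intensities - mean(intensities)
  s <- sd(m)
  if (!is.finite(s) || s == 0)
    stop_scn("cannot calibrate: intensities are all equal",
             class = "scn_degenerate_error")
  O <- function(alpha) order_parameter(alpha * m)

  # Walk down the initial monotone-decreasing branch from O(0) = 1 until the
  # target is bracketed.
  step <- 0.05 / s
  prev_alpha <- 0
  prev_O <- 1
  bracket <- NULL
  for (k in seq_len(5000L)) {
    alpha <- k * step
    val <- O(alpha)
    if (val <= target) { bracket <- c(prev_alpha, alpha); break }
    if (val > prev_O + 1e-12)
      stop_scn("cannot calibrate: order parameter rises above the target ",
               "before reaching it (target below the first-branch minimum)",
               class = "scn_calibration_error")
    prev_alpha <- alpha
    prev_O <- val
  }
  if (is.null(bracket))
    stop_scn("cannot calibrate: target not reached on the first branch",
             class = "scn_calibration_error")
  root <- uniroot(function(a) O(a) - target, interval = bracket,
                  tol = min(tol * max(1, 1 / s), 1e-7 * step))
  alpha_cal <- root$root
  achieved <- O(alpha_cal)
  if (abs(achieved - target) > 1e-6)
    stop_scn("calibration did not converge: |achieved - target| = ",
             format(abs(achieved - target)), class = "scn_calibration_error")
  structure(list(
    alpha_cal = alpha_cal, target = target, achieved = achieved,
    n = length(m),
    fingerprint = intensity_fingerprint(intensities)
  ), class = "scn_calibration")
}

intensity_fingerprint <- function(intensities) {
  c(n = length(intensities),
    mean = mean(intensities),
    sd = sd(intensities))
}

#' @export
print.scn_calibration <- function(x, ...) {
  cat(sprintf(
    "<scn_calibration> alpha = %.6g rad/unit (%.6g h/unit), O = %.6f (target %.2f), n = %d\n",
    x$alpha_cal, radians_to_hours(x$alpha_cal), x$achieved, x$target, x$n
  ))
  invisible(x)
}
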