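# Snapshot analysis: applying the calibrated model to neuron tables,
# phase-distribution statistics and nearest-neighbour direction anisotropy.

#' Estimate per-neuron phases from a snapshot with a calibrated scale
#'
#' Applies the calibrated snapshot model \eqn{\phi_i = \alpha m_i} to the
#' mean-centered neuron intensities of a table. The calibration must have
#' been performed on the same intensities (guarded by a fingerprint); the
#' mean phase is zero by construction. Estimates outside (-12, 12] hours
#' indicate model extrapolation and trigger a warning, not clipping.
#'
#' @param table an [scn_neuron_table()].
#' @param scale an `scn_calibration` from [calibrate_alpha()] run on this
#'   table's intensities.
#' @return an object of class `scn_phase_estimates`: a `data.frame` with
#'   `neuron_id`, `phase_radians`, `phase_hours`, carrying the calibration as
#'   an attribute.
#' @export
estimate_snapshot_phases <- function(table, scale) {
  stopifnot(inherits(table, "scn_neuron_table"),
            inherits(scale, "scn_calibration"))
  fp <- intensity_fingerprint(table$intensity)
  if (!isTRUE(all.equal(fp, scale$fingerprint, tolerance = 1e-8)))
    stop_scn("calibration does not match this table's intensities ",
             "(recalibrate on this table)", class = "scn_mismatch_error")
  m <- table$intensity - mean(table$intensity)
  rad <- scale$alpha_cal * m
  hours <- radians_to_hours(rad)
  out_of_range <- abs(hours) > 12
  if (any(out_of_range))
    warning(sum(out_of_range),
            " estimated phase(s) outside (-12, 12] hours: model extrapolation")
  est <- data.frame(neuron_id = table$neuron_id, phase_radians = rad,
                    phase_hours = hours)
  attr(est, "calibration") <- scale
  class(est) <- c("scn_phase_estimates", "data.frame")
  est
}

#' Moment statistics of a phase distribution
#'
#' Mean, standard deviation, moment-based sample skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} and excess kurtosis
#' \eqn{g_2 = m_4 / m_2^2 - 3}. Skewness and excess kurtosis are scale-free,
#' so they do not depend on the calibration constant alpha.
#'
#' @param x an `scn_phase_estimates` (its `phase_hours` are used) or a
#'   numeric vector of phases.
#' @return a one-row `data.frame`: `n`, `mean`, `sd`, `skewness`,
#'   `excess_kurtosis` (the last two are `NA` for zero-variance input).
#' @export
phase_distribution_stats <- function(x) {
  v <- if (inherits(x, "scn_phase_estimates")) x$phase_hours else as.numeric(x)
  n <- length(v)
  if (n < 4)
    stop_scn("need at least 4 values", class = "scn_config_error")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 == 0)
    return(data.frame(n = n, mean = mu, sd = 0, skewness = NA_real_,
                      excess_kurtosis = NA_real_))
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  data.frame(n = n, mean = mu, sd = sd(v),
             skewness = m3 / m2^1.5,
             excess_kurtosis = m4 / m2^2 - 3)
}

#' Directions of short-range connections between neurons
#'
#' For every ordered pair of neurons (i, j), i != j, within `radius`
#' micrometres (Euclidean), the unit direction
#' \eqn{v_{ij} = (r_i - r_j) / \|r_i - r_j\|} and its spherical angles under
#' the parameterization
#' \eqn{v = (\cos\theta \sin\phi, \sin\theta \sin\phi, \cos\phi)}:
#' azimuth `theta` in (-pi, pi], polar `phi_sph` in [0, pi]. Because ordered
#' pairs are emitted, the direction multiset is antipodally symmetric.
#' Coincident neurons (zero distance) are skipped with a warning.
#'
#' @param table an [scn_neuron_table()] with at least 2 neurons.
#' @param radius connection radius in micrometres (default 20).
#' @return a `data.frame` with `i`, `j` (neuron ids), `vx`, `vy`, `vz`,
#'   `theta`, `phi_sph`.
#' @export
connection_directions <- function(table, radius = 20) {
  stopifnot(inherits(table, "scn_neuron_table"))
  if (nrow(table) < 2)
    stop_scn("need at least 2 neurons", class = "scn_config_error")
  if (radius <= 0)
    stop_scn("radius must be positive", class = "scn_config_error")
  xyz <- neuron_coords(table)
  pr <- radius_pairs_cpp(xyz[, 1], xyz[, 2], xyz[, 3], radius)
  if (length(pr$i) == 0)
    return(data.frame(i = integer(), j = integer(), vx = numeric(),
                      vy = numeric(), vz = numeric(), theta = numeric(),
                      phi_sph = numeric()))
  zero <- pr$dist == 0
  if (any(zero)) {
    warning(sum(zero), " coincident neuron pair(s) skipped (zero distance)")
    pr <- lapply(pr, function(v) v[!zero])
  }
  # Unordered pairs (i < j) from C++; emit both orders.
  i <- c(pr$i, pr$j); j <- c(pr$j, pr$i)
  d <- c(pr$dist, pr$dist)
  v <- (xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]) / d
  data.frame(i = table$neuron_id[i], j = table$neuron_id[j],
             vx = v[, 1], vy = v[, 2], vz = v[, 3],
             theta = atan2(v[, 2], v[, 1]),
             phi_sph = acos(pmin(pmax(v[, 3], -1), 1)))
}

#' Two-dimensional histogram of connection directions
#'
#' Bins spherical angles into an equal-width grid over azimuth
#' theta in (-pi, pi] and polar phi in [0, pi] (35 x 35 by default, matching
#' the anisotropy maps). Raw angle bins are uncorrected for solid angle: a
#' truly isotropic direction field is proportional to sin(phi) in these
#' coordinates, not flat; the optional solid-angle density divides each bin
#' fraction by its spherical area for an isotropy-flat rendering.
#'
#' @param directions output of [connection_directions()], or a two-column
#'   matrix/data.frame of (theta, phi_sph).
#' @param n_bins bins per axis (default 35).
#' @return an object of class `scn_direction_histogram`: `count` and
#'   `fraction` matrices (rows = theta bins, columns = phi bins; fractions
#'   sum to 1), `solid_angle_density` (fraction per steradian), and the
#'   breaks.
#' @export
direction_histogram <- function(directions, n_bins = 35) {
  if (is.data.frame(directions) && all(c("theta", "phi_sph") %in%
                                       names(directions))) {
    th <- directions$theta; ph <- directions$phi_sph
  } else {
    directions <- as.matrix(directions)
    th <- directions[, 1]; ph <- directions[, 2]
  }
  if (length(th) == 0)
    stop_scn("empty direction list", class = "scn_config_error")
  tb <- seq(-pi, pi, length.out = n_bins + 1)
  pb <- seq(0, pi, length.out = n_bins + 1)
  ti <- findInterval(th, tb, left.open = TRUE, rightmost.closed = FALSE)
  ti[ti == 0L] <- 1L                      # theta = -pi folds into the first bin
  pi_idx <- findInterval(ph, pb, rightmost.closed = TRUE)
  count <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ti))
    count[ti[k], pi_idx[k]] <- count[ti[k], pi_idx[k]] + 1L
  fraction <- count / sum(count)
  # Bin solid angle: dOmega = dtheta * (cos(phi_lo) - cos(phi_hi)).
  dtheta <- diff(tb)
  dcos <- cos(pb[-(n_bins + 1)]) - cos(pb[-1])
  omega <- outer(dtheta, dcos)
  structure(list(count = count, fraction = fraction,
                 solid_angle_density = fraction / omega,
                 theta_breaks = tb, phi_breaks = pb),
            class = "scn_direction_histogram")
}

#' @export
print.scn_direction_histogram <- function(x, ...) {
  cat(sprintf("<scn_direction_histogram> %d x %d bins, %d directions\n",
              nrow(x$count), ncol(x$count), sum(x$count)))
  invisible(x)
}

#' Fraction of directions near the horizontal plane
#'
#' Convenience summary of anisotropy: the fraction of connection directions
#' whose polar angle lies within `half_width` of pi/2, together with the
#' expectation under isotropy (`sin(half_width)`).
#'
#' @param directions output of [connection_directions()].
#' @param half_width half-width of the polar band in radians (default pi/7).
#' @return a list with `fraction` and `isotropic_expectation`.
#' @export
equatorial_fraction <- function(directions, half_width = pi / 7) {
  ph <- directions$phi_sph
  if (length(ph) == 0)
    stop_scn("empty direction list", class = "scn_config_error")
  list(fraction = mean(abs(ph - pi / 2) < half_width),
       isotropic_expectation = sin(half_width))
}
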