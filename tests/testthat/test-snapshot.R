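# Snapshot phase estimation, distribution statistics and direction
# anisotropy.

test_that("estimated phases are the calibrated rescaling of centered intensity", {
  tab <- toy_table()
  cal <- calibrate_alpha(tab$intensity, target = 0.8)
  est <- suppressWarnings(estimate_snapshot_phases(tab, cal))
  m <- tab$intensity - mean(tab$intensity)
  expect_equal(est$phase_radians, cal$alpha_cal * m, tolerance = 1e-12)
  expect_equal(mean(est$phase_hours), 0, tolerance = 1e-12)
  expect_equal(order_parameter(est$phase_radians), 0.8, tolerance = 1e-6)

  # a neuron exactly at the mean intensity has phase 0
  tab5 <- scn_neuron_table(1:5, rnorm(5), rnorm(5), rnorm(5),
                           c(10, 20, 30, 40, 25))  # mean is 25
  cal5 <- calibrate_alpha(tab5$intensity, target = 0.8)
  est5 <- estimate_snapshot_phases(tab5, cal5)
  expect_equal(est5$phase_hours[5], 0)

  # direct product: alpha 0.5 rad/unit times centered intensity 2 -> 1 rad
  fake <- cal; fake$alpha_cal <- 0.5
  est2 <- suppressWarnings(estimate_snapshot_phases(tab, fake))
  expect_equal(est2$phase_radians[m == 5], 2.5)
})

test_that("calibration fingerprint guards against scale/table mismatch", {
  snap <- calibrated_snapshot(seed = 1, n_neurons = 300)
  other <- synth_snapshot(snapshot_synth_config(n_neurons = 300, seed = 9))
  expect_error(estimate_snapshot_phases(other$table, snap$cal),
               class = "scn_mismatch_error")
})

test_that("phase estimation is equivariant under intensity shift and scale", {
  snap <- calibrated_snapshot(seed = 3, n_neurons = 500)
  tab <- snap$table
  # additive shift: same calibration alpha, identical phases
  shifted <- tab; shifted$intensity <- tab$intensity + 1000
  cal_s <- calibrate_alpha(shifted$intensity, target = 0.8)
  est_s <- suppressWarnings(estimate_snapshot_phases(shifted, cal_s))
  expect_equal(est_s$phase_hours, snap$est$phase_hours, tolerance = 1e-6)
  # multiplicative rescale: recalibration absorbs the units
  scaled <- tab; scaled$intensity <- tab$intensity * 37
  cal_c <- calibrate_alpha(scaled$intensity, target = 0.8)
  est_c <- suppressWarnings(estimate_snapshot_phases(scaled, cal_c))
  expect_equal(est_c$phase_hours, snap$est$phase_hours, tolerance = 1e-6)
})

test_that("moment statistics match known distributions", {
  expect_equal(phase_distribution_stats(c(-1, 1, -1, 1))$skewness, 0)
  set.seed(4)
  x <- stats::rexp(1e5)
  st <- phase_distribution_stats(x)
  expect_equal(st$skewness, 2, tolerance = 0.2)
  expect_equal(st$excess_kurtosis, 6, tolerance = 1.5)
  expect_error(phase_distribution_stats(c(1, 2, 3)),
               class = "scn_config_error")
  flat <- phase_distribution_stats(rep(2, 10))
  expect_true(is.na(flat$skewness) && is.na(flat$excess_kurtosis))
})

test_that("skewness and kurtosis do not depend on the calibration target", {
  snap <- calibrated_snapshot(seed = 5, n_neurons = 800)
  st1 <- phase_distribution_stats(snap$est)
  cal2 <- calibrate_alpha(snap$table$intensity, target = 0.5)
  est2 <- suppressWarnings(estimate_snapshot_phases(snap$table, cal2))
  st2 <- phase_distribution_stats(est2)
  expect_equal(st1$skewness, st2$skewness, tolerance = 1e-9)
  expect_equal(st1$excess_kurtosis, st2$excess_kurtosis, tolerance = 1e-9)
  # default-condition clouds are right-skewed and leptokurtic
  expect_gt(st1$skewness, 0)
  expect_gt(st1$excess_kurtosis, 0)
})

test_that("connection directions follow the spherical parameterization", {
  tab <- scn_neuron_table(1:2, c(0, 0), c(0, 10), c(0, 0), c(1, 1))
  d <- connection_directions(tab, radius = 20)
  expect_equal(nrow(d), 2)  # both orders
  up <- d[d$vy > 0, ]
  expect_equal(c(up$vx, up$vy, up$vz), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(up$theta, pi / 2, tolerance = 1e-12)
  expect_equal(up$phi_sph, pi / 2, tolerance = 1e-12)
  # reconstruct v from the angles
  expect_equal(cos(up$theta) * sin(up$phi_sph), up$vx, tolerance = 1e-12)

  # out of radius: no directions
  far <- scn_neuron_table(1:2, c(0, 25), c(0, 0), c(0, 0), c(1, 1))
  expect_equal(nrow(connection_directions(far, radius = 20)), 0)

  # coincident neurons are skipped with a warning
  co <- scn_neuron_table(1:3, c(0, 0, 5), c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_warning(dco <- connection_directions(co, radius = 20), "coincident")
  expect_equal(nrow(dco), 4)
})

test_that("direction multiset is antipodally symmetric", {
  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 400, seed = 6))
  d <- connection_directions(snap$table, radius = 25)
  expect_gt(nrow(d), 0)
  v <- round(cbind(d$vx, d$vy, d$vz), 10)
  keys <- do.call(paste, as.data.frame(v))
  anti <- do.call(paste, as.data.frame(-v))
  expect_setequal(keys, anti)
  # histogram inherits the symmetry (theta, phi) -> (theta +- pi, pi - phi)
  # on a grid with an even theta bin count (a half turn is 18 of 36 bins)
  h <- direction_histogram(d, n_bins = 36)
  expect_equal(h$count, h$count[c(19:36, 1:18), 36:1])
})

test_that("direction histogram fractions sum to one and find lone directions", {
  one <- data.frame(theta = rep(1, 7), phi_sph = rep(2, 7))
  h <- direction_histogram(one)
  expect_equal(sum(h$count), 7)
  expect_equal(max(h$fraction), 1)
  expect_equal(sum(h$fraction), 1)

  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 600, seed = 7))
  h2 <- direction_histogram(connection_directions(snap$table, radius = 25))
  expect_equal(sum(h2$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(h2$count > 0) <= 35 * 35, TRUE)
})

test_that("isotropic directions are sin(phi)-weighted in raw angle bins", {
  set.seed(8)
  n <- 2e5
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  ang <- data.frame(theta = atan2(v[, 2], v[, 1]), phi_sph = acos(v[, 3]))
  h <- direction_histogram(ang)
  # marginal over theta: fraction in each phi bin tracks the solid angle
  phi_marg <- colSums(h$fraction)
  pb <- h$phi_breaks
  expected <- (cos(pb[-36]) - cos(pb[-1])) / 2
  expect_lt(max(abs(phi_marg - expected)), 0.003)
  # the solid-angle-corrected density is flat for isotropic input
  dens <- rowSums(h$count)  # theta marginal: uniform
  expect_lt(max(abs(dens / n - 1 / 35)), 0.005)
})
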