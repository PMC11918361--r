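# Fourier conventions, phase normalization, spectra, clustering, histograms.

test_that("circadian component recovers shifted cosines exactly", {
  # 48-point DFT of cos(2*pi*(t - s)/24) has bin 2 = 24 * exp(-i*2*pi*s/24),
  # so A = 1 and h = s by the shift theorem.
  for (shift in c(0, 3, -5, 11)) {
    g <- cosine_grid(shift = shift, amplitude = 2.5, baseline = 7)
    f <- circadian_component(g)
    expect_equal(f$amplitude[1, 1], 2.5, tolerance = 1e-12)
    expect_equal(f$phase_h[1, 1], wrap_hours(shift), tolerance = 1e-9)
    expect_true(all(f$defined[f$mask]))
  }
})

test_that("constant pixels are flagged undefined, not errors", {
  arr <- array(5, c(2, 2, 48))
  arr[1, 1, ] <- cos(2 * pi * (0:47) / 24)
  f <- circadian_component(scn_grid(arr))
  expect_true(f$defined[1, 1])
  expect_false(f$defined[2, 2])
  expect_equal(f$amplitude[2, 2], 0)
  expect_true(is.na(f$phase_h[2, 2]))
})

test_that("normalization is relative to the tissue mean, wraps, and is idempotent", {
  # Two equal-amplitude pixels at h = 2 and 4: the summed cosine has phase 3,
  # so normalized phases are -1 and +1.
  t <- 0:47
  arr <- array(0, c(1, 2, 48))
  arr[1, 1, ] <- cos(2 * pi * (t - 2) / 24)
  arr[1, 2, ] <- cos(2 * pi * (t - 4) / 24)
  g <- scn_grid(arr)
  f <- normalize_phases(circadian_component(g), g)
  expect_equal(f$phase_h[1, ], c(-1, 1), tolerance = 1e-9)

  # one-pixel grid is its own reference
  g1 <- cosine_grid(n_rows = 1, n_cols = 1, shift = 9)
  f1 <- normalize_phases(circadian_component(g1), g1)
  expect_equal(f1$phase_h[1, 1], 0, tolerance = 1e-9)

  # idempotent
  f2 <- normalize_phases(f, g)
  expect_identical(f2$phase_h, f$phase_h)

  # wrap rule: raw 11 vs reference -11 -> -2, not 22
  expect_equal(wrap_hours(11 - (-11)), -2)

  # undefined reference errors
  flat <- scn_grid(array(1, c(2, 2, 48)))
  expect_error(normalize_phases(circadian_component(flat), flat),
               class = "scn_degenerate_error")
})

test_that("power spectrum satisfies Parseval and splits equal components", {
  t <- 0:47
  ps <- power_spectrum(cos(2 * pi * t / 24))
  expect_equal(ps$power[ps$period_h == 24], 0.5, tolerance = 1e-12)
  expect_equal(sum(ps$power[ps$period_h != 24]), 0, tolerance = 1e-12)

  x <- 3 * cos(2 * pi * t / 24) + 3 * cos(2 * pi * (t - 5) / 12)
  ps2 <- power_spectrum(x)
  expect_equal(ps2$power[ps2$period_h == 24], ps2$power[ps2$period_h == 12],
               tolerance = 1e-12)
  expect_equal(circadian_power_fraction(x), 0.5, tolerance = 1e-12)

  # Parseval: bin powers sum to the population variance, for any series.
  set.seed(5)
  y <- rnorm(48)
  expect_equal(sum(power_spectrum(y)$power), mean((y - mean(y))^2),
               tolerance = 1e-12)

  # white noise spreads power: no bin dominates
  expect_lt(max(power_spectrum(y)$power) / sum(power_spectrum(y)$power), 0.5)

  expect_equal(circadian_power_fraction(cos(2 * pi * t / 24)), 1,
               tolerance = 1e-12)
  expect_true(is.na(circadian_power_fraction(rep(5, 48))))
  expect_error(power_spectrum(rnorm(47)),
               class = "scn_insufficient_data_error")
})

test_that("phase recovery is exact without noise and unbiased with noise", {
  # exact oracle equivalence (no noise, no decay): raw phase - 12 h offset
  # equals the generated phase to numerical tolerance
  sim <- synth_slice_timeseries(slice_synth_config(noise_sd = 0,
                                                   decay_tau = Inf, seed = 3))
  f <- circadian_component(sim$grid)
  raw <- f$phase_h[cbind(sim$truth$row, sim$truth$col)]
  expect_lt(max(abs(wrap_hours(raw - 12 - sim$truth$phase_h))), 1e-6)

  # with 10% noise: small RMSE, mean error below 0.05 h over all pixels
  sim2 <- synth_slice_timeseries(slice_synth_config(seed = 11))
  f2 <- normalize_phases(circadian_component(sim2$grid), sim2$grid)
  err <- wrap_hours(f2$phase_h[cbind(sim2$truth$row, sim2$truth$col)] -
                      sim2$truth$phase_h)
  expect_gt(length(err), 1000)
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_lt(abs(mean(err)), 0.05)
})

test_that("per-pixel circadian reconstruction satisfies the Parseval identity", {
  sim <- synth_slice_timeseries(slice_synth_config(
    n_rows = 14, n_cols = 14, mask_semiaxes = c(6, 5), seed = 9))
  f <- circadian_component(sim$grid)
  idx <- which(sim$grid$mask, arr.ind = TRUE)[1:5, , drop = FALSE]
  for (i in seq_len(nrow(idx))) {
    x <- sim$grid$intensity[idx[i, 1], idx[i, 2], 1:48]
    ps <- power_spectrum(x)
    # residual power = total non-DC power minus the 24-h bin, exactly
    recon <- mean(x) + f$amplitude[idx[i, 1], idx[i, 2]] *
      cos(2 * pi * ((0:47) - f$phase_h[idx[i, 1], idx[i, 2]]) / 24)
    resid_var <- mean((x - recon)^2)
    expect_equal(resid_var, sum(ps$power) - ps$power[ps$period_h == 24],
                 tolerance = 1e-9)
    # and the 24-h component explains at least its share of variance
    expect_gte(ps$power[ps$period_h == 24] / sum(ps$power) + 1e-12,
               1 - resid_var / mean((x - mean(x))^2))
  }
})

test_that("k-means recovers noiseless phase blocks and orders labels by peak", {
  # two spatial blocks with phases 0 and 4 h
  t <- 0:47
  arr <- array(0, c(4, 4, 48))
  for (r in 1:4) for (c in 1:4) {
    shift <- if (c <= 2) 0 else 4
    arr[r, c, ] <- cos(2 * pi * (t - shift) / 24)
  }
  g <- scn_grid(arr)
  cl <- cluster_pixels(g, k = 2, seed = 1)
  expect_true(all(cl$label[, 1:2] == 1))
  expect_true(all(cl$label[, 3:4] == 2))
  expect_equal(cl$peak_time_h, c(0, 4), tolerance = 1e-9)
  # label 1 has the earliest peak by contract
  expect_true(!is.unsorted(cl$peak_time_h))

  expect_error(cluster_pixels(g, k = 20), class = "scn_config_error")
  expect_error(cluster_pixels(g, k = 1), class = "scn_config_error")
})

test_that("cluster peak ordering holds on heterogeneous synthetic tissue", {
  sim <- synth_slice_timeseries(slice_synth_config(gradient_span = 4, seed = 5))
  cl <- cluster_pixels(sim$grid, k = 5, seed = 2)
  expect_true(!is.unsorted(cl$peak_time_h))
  expect_setequal(unique(cl$label[sim$grid$mask]), 1:5)
  expect_true(all(is.na(cl$label[!sim$grid$mask])))
})

test_that("phase histogram conserves counts and respects the gradient bound", {
  sim <- synth_slice_timeseries(slice_synth_config(gradient_span = 5,
                                                   seed = 6))
  f <- normalize_phases(circadian_component(sim$grid), sim$grid)
  h <- phase_histogram(f, bin_width = 0.5)
  expect_equal(sum(h$count), sum(sim$grid$mask))
  # tight gradient + jitter stays within a 5-hour advance/delay
  occupied <- h[h$count > 0, ]
  expect_true(all(occupied$bin_lo >= -5 & occupied$bin_hi <= 5))

  # all-zero phases occupy a single bin
  g0 <- cosine_grid(n_rows = 2, n_cols = 2)
  f0 <- normalize_phases(circadian_component(g0), g0)
  h0 <- phase_histogram(f0)
  expect_equal(sum(h0$count > 0), 1)
  expect_equal(sum(h0$count), 4)
})
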