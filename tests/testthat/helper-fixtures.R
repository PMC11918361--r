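# Shared fixtures, built in code at test time.

# A tiny pure-cosine grid: every masked pixel A*cos(2*pi*(t - shift)/24) + C.
cosine_grid <- function(n_rows = 3, n_cols = 3, shift = 0, amplitude = 1,
                        baseline = 0, n_frames = 48, mask = NULL) {
  t <- seq_len(n_frames) - 1
  x <- baseline + amplitude * cos(2 * pi * (t - shift) / 24)
  arr <- array(rep(x, each = n_rows * n_cols), c(n_rows, n_cols, n_frames))
  scn_grid(arr, mask = mask)
}

# Small deterministic neuron table.
toy_table <- function() {
  scn_neuron_table(
    neuron_id = 1:4,
    x_um = c(0, 10, 0, 0),
    y_um = c(0, 0, 10, 0),
    z_um = c(0, 0, 0, 10),
    intensity = c(10, 20, 30, 40)
  )
}

rskewnorm_local <- function(n, location = 0, scale = 1, shape = 0)
  scnphase:::rskewnorm(n, location, scale, shape)

# Default-condition synthetic snapshot with calibrated phase estimates.
calibrated_snapshot <- function(seed = 1, n_neurons = 3000, ...) {
  sim <- synth_snapshot(snapshot_synth_config(seed = seed,
                                              n_neurons = n_neurons, ...))
  cal <- calibrate_alpha(sim$table$intensity)
  est <- suppressWarnings(estimate_snapshot_phases(sim$table, cal))
  list(table = sim$table, truth = sim$truth, cal = cal, est = est)
}
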