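# Synthetic slice time-series generator: tightly phase-clustered 24-h
# oscillators on an elliptical tissue mask, with amplitude heterogeneity,
# waveform asymmetry, slow decay and additive noise.

#' Configuration for the synthetic slice movie generator
#'
#' The generator emulates an hourly PER2::LUC movie of one SCN slice. Each
#' in-tissue pixel p follows
#' \deqn{I_p(t) = C + A_p e^{-t/\tau} w(2\pi (t - \phi_p - 12)/24) + \epsilon_t}
#' with waveform \eqn{w(\theta) = \cos\theta + a_2 \cos(2\theta - \pi/2)}
#' , i.e. \eqn{w(\theta) = \cos\theta (1 + 2 a_2 \sin\theta)}: a 24-hour
#' cosine whose falling limb is steepened by the second-harmonic term,
#' mirroring the rapid degradation phase of PER2 (pure cosine at
#' `asymmetry = 0`). The 12-hour offset places the global-mean trough at
#' t = 0, the CT0000 convention. Phases are a medial-lateral spatial gradient
#' plus skew-normal jitter, centred so the masked-pixel mean is zero.
#'
#' @param n_rows,n_cols grid shape in pixels.
#' @param n_frames number of hourly frames (>= 48).
#' @param frame_interval hours between frames.
#' @param mask_semiaxes semi-axes (rows, cols) of the elliptical tissue mask,
#'   in pixels.
#' @param amplitude_mean,amplitude_cv mean and coefficient of variation of the
#'   lognormal per-pixel amplitude.
#' @param baseline additive constant C (not subject to decay).
#' @param gradient_span phase span in hours across the masked columns (a
#'   left-to-right phase wave); 0 disables the gradient.
#' @param jitter_location,jitter_scale,jitter_skew skew-normal phase jitter
#'   parameters (hours); the skew lets the phase distribution mirror the
#'   right-skew seen in tissue.
#' @param noise_sd additive Gaussian noise standard deviation, as a fraction
#'   of the pixel amplitude.
#' @param decay_tau decay time constant in hours (multiplicative on the
#'   oscillatory part only); `Inf` disables decay.
#' @param asymmetry relative weight of the second harmonic in the waveform.
#' @param orientation slice orientation label.
#' @param seed RNG seed.
#' @return a list of class `scn_slice_synth_config`.
#' @export
slice_synth_config <- function(n_rows = 60, n_cols = 60, n_frames = 48,
                               frame_interval = 1,
                               mask_semiaxes = c(27, 22),
                               amplitude_mean = 100, amplitude_cv = 0.2,
                               baseline = 300,
                               gradient_span = 2,
                               jitter_location = 0, jitter_scale = 0.8,
                               jitter_skew = 4,
                               noise_sd = 0.1,
                               decay_tau = 96,
                               asymmetry = 0.15,
                               orientation = "coronal",
                               seed = 1L) {
  if (amplitude_mean <= 0 || amplitude_cv < 0)
    stop_scn("amplitude mean must be positive and CV nonnegative",
             class = "scn_config_error")
  if (noise_sd < 0)
    stop_scn("noise sd must be nonnegative", class = "scn_config_error")
  if (n_frames < 48)
    stop_scn("need n_frames >= 48", class = "scn_config_error")
  if (decay_tau <= 0)
    stop_scn("decay_tau must be positive (Inf disables decay)",
             class = "scn_config_error")
  structure(as.list(environment()), class = "scn_slice_synth_config")
}

#' Generate a synthetic slice time-series movie with ground truth
#'
#' @param cfg a [slice_synth_config()].
#' @return a list with elements `grid` (an [scn_grid()]) and `truth` (a
#'   `data.frame` with `row`, `col`, `phase_h` (hours, masked-pixel mean
#'   zero), `amplitude` and `baseline` for every in-tissue pixel).
#' @examples
#' sim <- synth_slice_timeseries(slice_synth_config(seed = 7))
#' sim$grid
#' @export
synth_slice_timeseries <- function(cfg = slice_synth_config()) {
  stopifnot(inherits(cfg, "scn_slice_synth_config"))
  set.seed(cfg$seed)
  rows <- seq_len(cfg$n_rows)
  cols <- seq_len(cfg$n_cols)
  cr <- (cfg$n_rows + 1) / 2
  cc <- (cfg$n_cols + 1) / 2
  mask <- outer(rows, cols, function(r, c) {
    ((r - cr) / cfg$mask_semiaxes[1])^2 +
      ((c - cc) / cfg$mask_semiaxes[2])^2 <= 1
  })
  if (!any(mask))
    stop_scn("mask semi-axes give an empty mask", class = "scn_config_error")
  idx <- which(mask, arr.ind = TRUE)
  np <- nrow(idx)

  # Phase field: linear column gradient spanning `gradient_span` hours across
  # the masked column range, plus skew-normal jitter; centred to mean zero.
  mc <- range(idx[, "col"])
  grad <- if (cfg$gradient_span == 0 || mc[1] == mc[2]) rep(0, np) else
    cfg$gradient_span * (idx[, "col"] - mc[1]) / (mc[2] - mc[1]) -
      cfg$gradient_span / 2
  jit <- rskewnorm(np, cfg$jitter_location, cfg$jitter_scale, cfg$jitter_skew)
  phase <- grad + jit
  phase <- phase - mean(phase)

  # Lognormal amplitudes with the requested mean and CV.
  amp <- if (cfg$amplitude_cv == 0) rep(cfg$amplitude_mean, np) else {
    s2 <- log(1 + cfg$amplitude_cv^2)
    rlnorm(np, meanlog = log(cfg$amplitude_mean) - s2 / 2, sdlog = sqrt(s2))
  }

  tt <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  theta <- outer(phase, tt, function(p, t) 2 * pi * (t - p - 12) / 24)
  waveform <- cos(theta) + cfg$asymmetry * cos(2 * theta - pi / 2)
  decay <- exp(-tt / cfg$decay_tau)
  signal <- cfg$baseline +
    amp * waveform * rep(decay, each = np)
  if (cfg$noise_sd > 0)
    signal <- signal + rnorm(length(signal), sd = cfg$noise_sd * amp)

  arr <- array(0, c(cfg$n_rows, cfg$n_cols, cfg$n_frames))
  flat <- (idx[, "col"] - 1) * cfg$n_rows + idx[, "row"]
  for (t in seq_len(cfg$n_frames)) {
    frame <- matrix(0, cfg$n_rows, cfg$n_cols)
    frame[flat] <- signal[, t]
    arr[, , t] <- frame
  }
  grid <- scn_grid(arr, mask = mask, frame_interval = cfg$frame_interval,
                   orientation = cfg$orientation)
  truth <- data.frame(row = idx[, "row"], col = idx[, "col"],
                      phase_h = phase, amplitude = amp,
                      baseline = cfg$baseline)
  list(grid = grid, truth = truth)
}
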