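# Fourier analysis of slice movies: the 24-hour component per pixel, power
# spectra, circadian power fraction, latency-ordered clustering and phase
# histograms.
#
# Conventions, pinned by tests on shifted-cosine fixtures:
# the 48-point DFT bin k = 2 carries the 24-hour component; writing
# X2 = sum_t x_t exp(-2 pi i * 2 t / 48), the reconstruction of the component
# is A cos(2 pi (t - h) / 24) with A = 2 |X2| / 48 and h = -Arg(X2) * 24/(2 pi)
# wrapped into (-12, 12]. Phase is computed with atan2 (full quadrant), not a
# plain arctangent, so shifts larger than 6 hours resolve correctly.

DFT_FRAMES <- 48L
CIRCADIAN_BIN <- 2L

dft_bin <- function(x, k, n = DFT_FRAMES) {
  t <- seq_len(n) - 1
  sum(x[seq_len(n)] * exp(-2i * pi * k * t / n))
}

# Amplitude/phase of the 24-h component of one series (first 48 frames).
circadian_of_series <- function(x, tol = NULL) {
  X2 <- dft_bin(x, CIRCADIAN_BIN)
  a <- Re(X2)
  b <- Im(X2)
  A <- 2 * Mod(X2) / DFT_FRAMES
  if (is.null(tol)) tol <- 1e-12 * max(1, mean(abs(x[seq_len(DFT_FRAMES)])))
  defined <- A > tol
  h <- if (defined) wrap_hours(-Arg(X2) * 24 / (2 * pi)) else NA_real_
  list(a = a, b = b, amplitude = A, phase_h = h, defined = defined)
}

#' Per-pixel circadian component of a slice movie
#'
#' Computes, for every in-tissue pixel, the 24-hour discrete Fourier
#' component of the first 48 hourly frames: the Fourier pair (a, b), the
#' amplitude \eqn{A = \sqrt{a^2 + b^2}} (scaled so the component reconstructs
#' as \eqn{A \cos(2\pi (t - h)/24)}), the phase in hours, and the fraction of
#' non-DC power in the 24-hour bin. Pixels with zero 24-hour amplitude (e.g.
#' constant series) are flagged as having undefined phase rather than
#' raising an error.
#'
#' Raw phases are relative to the start of the recording; use
#' [normalize_phases()] to express them relative to the tissue-mean
#' oscillation (the convention in which downstream analyses operate).
#'
#' @param grid an [scn_grid()] with at least 48 hourly frames.
#' @return an object of class `scn_circadian_field`: per-pixel matrices `a`,
#'   `b`, `amplitude`, `phase_h`, `power_fraction`, logical `defined`, plus
#'   the mask and normalization state.
#' @export
circadian_component <- function(grid) {
  stopifnot(inherits(grid, "scn_grid"))
  if (n_frames(grid) < DFT_FRAMES)
    stop_scn("insufficient data: need >= 48 frames",
             class = "scn_insufficient_data_error")
  dm <- dim(grid$intensity)
  shape <- function() matrix(NA_real_, dm[1], dm[2])
  a <- shape(); b <- shape(); amp <- shape(); ph <- shape(); pf <- shape()
  defined <- matrix(NA, dm[1], dm[2])
  idx <- which(grid$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    x <- grid$intensity[r, c, seq_len(DFT_FRAMES)]
    cc <- circadian_of_series(x)
    a[r, c] <- cc$a; b[r, c] <- cc$b
    amp[r, c] <- cc$amplitude; ph[r, c] <- cc$phase_h
    defined[r, c] <- cc$defined
    pf[r, c] <- circadian_power_fraction(x)
  }
  structure(
    list(a = a, b = b, amplitude = amp, phase_h = ph, raw_phase_h = ph,
         power_fraction = pf, defined = defined, mask = grid$mask,
         normalized = FALSE, reference_phase_h = NA_real_),
    class = "scn_circadian_field"
  )
}

#' @export
print.scn_circadian_field <- function(x, ...) {
  cat(sprintf(
    "<scn_circadian_field> %d pixels, %s phases, median power fraction %.3f\n",
    sum(x$mask), if (x$normalized) "normalized" else "raw",
    stats::median(x$power_fraction[x$mask], na.rm = TRUE)
  ))
  invisible(x)
}

#' Normalize phases to the tissue-mean oscillation
#'
#' Re-expresses per-pixel phases relative to the phase of the spatial-mean
#' signal, so that a phase of zero corresponds to the mean oscillation across
#' the tissue and every pixel is at most 12 hours advanced or delayed.
#' Idempotent: normalization always starts from the stored raw phases.
#'
#' @param field an `scn_circadian_field` from [circadian_component()].
#' @param reference an [scn_grid()] (the tissue-mean series is computed over
#'   its mask) or a numeric series of at least 48 hourly samples.
#' @return the field with `phase_h` replaced by normalized phases in
#'   `(-12, 12]` and `normalized = TRUE`.
#' @export
normalize_phases <- function(field, reference) {
  stopifnot(inherits(field, "scn_circadian_field"))
  series <- if (inherits(reference, "scn_grid")) tissue_mean_series(reference)
            else as.numeric(reference)
  if (length(series) < DFT_FRAMES)
    stop_scn("reference series needs >= 48 samples",
             class = "scn_insufficient_data_error")
  ref <- circadian_of_series(series)
  if (!ref$defined)
    stop_scn("reference series has zero circadian amplitude: ",
             "reference phase undefined", class = "scn_degenerate_error")
  field$phase_h <- wrap_hours(field$raw_phase_h - ref$phase_h)
  field$normalized <- TRUE
  field$reference_phase_h <- ref$phase_h
  field
}

#' Fourier power spectrum of a single series
#'
#' Power per nonzero-frequency bin of the 48-point DFT (DC excluded), scaled
#' so that a pure cosine of amplitude A contributes A^2/2 at its bin and the
#' bin powers sum to the population variance of the series (Parseval).
#'
#' @param series numeric vector with at least 48 hourly samples (the first 48
#'   are used).
#' @return a `data.frame` with `k`, `period_h` and `power`.
#' @export
power_spectrum <- function(series) {
  if (length(series) < DFT_FRAMES)
    stop_scn("need >= 48 samples", class = "scn_insufficient_data_error")
  x <- as.numeric(series[seq_len(DFT_FRAMES)])
  X <- fft(x)
  n <- DFT_FRAMES
  k <- seq_len(n / 2)
  power <- ifelse(k < n / 2, 2 * Mod(X[k + 1])^2 / n^2, Mod(X[k + 1])^2 / n^2)
  data.frame(k = k, period_h = n / k, power = power)
}

#' Fraction of non-DC power in the 24-hour bin
#'
#' @param series numeric vector with at least 48 hourly samples.
#' @return a number in \[0, 1\], or `NA` when the series has zero non-DC
#'   power (e.g. a constant series).
#' @export
circadian_power_fraction <- function(series) {
  ps <- power_spectrum(series)
  total <- sum(ps$power)
  if (total <= 0) return(NA_real_)
  ps$power[ps$k == CIRCADIAN_BIN] / total
}

#' Cluster pixels by their time-series shape, ordered by peak latency
#'
#' k-means on per-pixel z-scored time series (fixed seed, 10 restarts),
#' with cluster labels re-ordered so that label 1 has the earliest
#' cluster-mean circadian peak time.
#'
#' @param grid an [scn_grid()].
#' @param k number of clusters (>= 2, at most the number of masked pixels).
#' @param seed RNG seed for the k-means restarts.
#' @return an object of class `scn_clusters`: integer `label` matrix (`NA`
#'   outside the mask, labels `1..k` ordered by nondecreasing peak time) and
#'   `peak_time_h` per label.
#' @export
cluster_pixels <- function(grid, k = 5, seed = 1L) {
  stopifnot(inherits(grid, "scn_grid"))
  if (k < 2) stop_scn("need k >= 2", class = "scn_config_error")
  series <- masked_series(grid)
  if (k > nrow(series))
    stop_scn("k exceeds the number of masked pixels",
             class = "scn_config_error")
  z <- t(apply(series, 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = 10, iter.max = 100)

  # Peak time of each cluster: circadian reconstruction of the cluster-mean
  # raw series peaks at t = h (mod 24).
  peak <- vapply(seq_len(k), function(cl) {
    m <- colMeans(series[km$cluster == cl, , drop = FALSE])
    cc <- circadian_of_series(m)
    if (!cc$defined) return(Inf)
    cc$phase_h %% 24
  }, numeric(1))
  ord <- order(peak)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)

  lab <- matrix(NA_integer_, nrow(grid$mask), ncol(grid$mask))
  lab[grid$mask] <- relabel[km$cluster]
  structure(list(label = lab, k = k, peak_time_h = peak[ord]),
            class = "scn_clusters")
}

#' @export
print.scn_clusters <- function(x, ...) {
  cat(sprintf("<scn_clusters> k = %d, peak times (h): %s\n", x$k,
              paste(sprintf("%.2f", x$peak_time_h), collapse = ", ")))
  invisible(x)
}

#' Histogram of normalized phases
#'
#' Counts of per-pixel normalized phases over `(-12, 12]` in equal-width
#' bins; counts sum to the number of masked pixels with defined phase.
#'
#' @param field a normalized `scn_circadian_field`.
#' @param bin_width bin width in hours (must divide 24).
#' @return a `data.frame` with `bin_lo`, `bin_hi`, `bin_mid`, `count`.
#' @export
phase_histogram <- function(field, bin_width = 0.5) {
  stopifnot(inherits(field, "scn_circadian_field"))
  if (!field$normalized)
    stop_scn("phases must be normalized first (see normalize_phases)",
             class = "scn_config_error")
  nb <- round(24 / bin_width)
  if (abs(nb * bin_width - 24) > 1e-9)
    stop_scn("bin width must divide 24 hours", class = "scn_config_error")
  breaks <- seq(-12, 12, length.out = nb + 1)
  ph <- field$phase_h[field$mask]
  ph <- ph[!is.na(ph)]
  # (-12, 12] bins: left-open, right-closed.
  bin <- findInterval(ph, breaks, left.open = TRUE, rightmost.closed = FALSE)
  bin[bin == 0L] <- 1L  # phase exactly -12 cannot occur after wrapping
  count <- tabulate(bin, nbins = nb)
  data.frame(bin_lo = breaks[-(nb + 1)], bin_hi = breaks[-1],
             bin_mid = (breaks[-(nb + 1)] + breaks[-1]) / 2, count = count)
}

#' Locate the trough of the tissue-mean oscillation
#'
#' CT0000 is defined as the trough of PER2::LUC expression. The trough is the
#' argmin over integer hours in the first 24 h of the circadian
#' reconstruction of the tissue-mean series (mean + A cos(2 pi (t - h)/24)).
#'
#' @param grid an [scn_grid()].
#' @return integer hour in `0..23` (0-based frame offset of the trough).
#' @export
find_trough <- function(grid) {
  stopifnot(inherits(grid, "scn_grid"))
  m <- tissue_mean_series(grid)
  cc <- circadian_of_series(m)
  if (!cc$defined)
    stop_scn("tissue-mean series has no circadian component: trough undefined",
             class = "scn_degenerate_error")
  t <- 0:23
  recon <- mean(m[seq_len(DFT_FRAMES)]) +
    cc$amplitude * cos(2 * pi * (t - cc$phase_h) / 24)
  t[which.min(recon)]
}
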