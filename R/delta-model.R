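# The brightness-difference / phase-difference linear model:
# Delta I = slope * Delta phi + c + eps,
# fitted on binned pixel pairs from a single movie frame, plus the hourly
# model scan from the trough.

#' Preprocess one movie frame into binned intensity/phase pairs
#'
#' The five preprocessing steps applied to a single frame before fitting the
#' model: (1) z-score the intensity values across the in-tissue pixels,
#' (2) remove the 10% highest and 10% lowest intensities, (3) sort the
#' remaining values into 400 equal-width bins over the trimmed range
#' (empty bins are dropped), (4) take pairwise differences of bin centers as
#' Delta I, (5) take the difference of per-bin mean phases as Delta phi.
#' All ordered pairs of distinct bins are emitted, so the pair set is
#' antisymmetric: for every (Delta I, Delta phi) the pair
#' (-Delta I, -Delta phi) is also present.
#'
#' @param intensity a single movie frame: numeric matrix, or a vector of
#'   masked-pixel values.
#' @param phases a normalized `scn_circadian_field`, or a numeric vector of
#'   phases (hours) aligned with `intensity`.
#' @param mask logical matrix when `intensity` is a matrix; defaults to the
#'   field's mask.
#' @param n_bins number of intensity bins (default 400).
#' @param trim fraction trimmed from each intensity tail (default 0.1).
#' @return an object of class `scn_binned_pairs`: `bins` (`center`,
#'   `mean_phase`, `n`) and `pairs` (`d_intensity`, `d_phase`).
#' @export
preprocess_bins <- function(intensity, phases, mask = NULL, n_bins = 400,
                            trim = 0.1) {
  if (inherits(phases, "scn_circadian_field")) {
    if (!phases$normalized)
      stop_scn("phases must be normalized first (see normalize_phases)",
               class = "scn_config_error")
    if (is.null(mask)) mask <- phases$mask
    ph <- phases$phase_h[mask]
  } else {
    ph <- as.numeric(phases)
  }
  val <- if (is.matrix(intensity)) {
    if (is.null(mask))
      stop_scn("a mask is required with a matrix frame",
               class = "scn_config_error")
    intensity[mask]
  } else as.numeric(intensity)
  if (length(val) != length(ph))
    stop_scn("frame and phases must share the mask",
             class = "scn_format_error")
  keep <- !is.na(ph) & is.finite(val)
  val <- val[keep]; ph <- ph[keep]
  n <- length(val)
  if (n < 2 || sd(val) == 0)
    stop_scn("degenerate binning: frame is constant over the mask",
             class = "scn_degenerate_error")

  z <- (val - mean(val)) / sd(val)
  ord <- order(z)
  n_trim <- floor(trim * n)
  kept <- ord[seq(n_trim + 1, n - n_trim)]
  if (length(kept) < n_bins)
    stop_scn("too few pixels (", length(kept), ") for ", n_bins,
             " bins; use a smaller bin count", class = "scn_config_error")
  zk <- z[kept]; pk <- ph[kept]

  breaks <- seq(min(zk), max(zk), length.out = n_bins + 1)
  bin <- findInterval(zk, breaks, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  centers <- (breaks[-(n_bins + 1)] + breaks[-1]) / 2
  occupied <- sort(unique(bin))
  mean_phase <- vapply(occupied, function(b) mean(pk[bin == b]), numeric(1))
  bins <- data.frame(center = centers[occupied], mean_phase = mean_phase,
                     n = as.integer(tabulate(bin, n_bins)[occupied]))
  binned_pair_set(bins, n_bins_requested = n_bins, trim = trim,
                  n_pixels = n)
}

#' Build the ordered-pair set from a bin table
#'
#' Expands per-bin (center, mean phase) values into all ordered pairs of
#' distinct bins. Exposed so that model fits can be driven from explicit bin
#' tables in tests and examples.
#'
#' @param bins a `data.frame` with columns `center`, `mean_phase` and
#'   optionally `n` (bin occupancy).
#' @param n_bins_requested,trim,n_pixels provenance fields.
#' @return an `scn_binned_pairs` object.
#' @export
binned_pair_set <- function(bins, n_bins_requested = nrow(bins), trim = NA,
                            n_pixels = sum(bins$n %||% NA)) {
  stopifnot(is.data.frame(bins), all(c("center", "mean_phase") %in% names(bins)))
  if (is.null(bins$n)) bins$n <- 1L
  B <- nrow(bins)
  ij <- expand.grid(i = seq_len(B), j = seq_len(B))
  ij <- ij[ij$i != ij$j, ]
  pairs <- data.frame(
    d_intensity = bins$center[ij$i] - bins$center[ij$j],
    d_phase = bins$mean_phase[ij$i] - bins$mean_phase[ij$j]
  )
  structure(list(bins = bins, pairs = pairs,
                 n_bins_requested = n_bins_requested, trim = trim,
                 n_pixels = n_pixels),
            class = "scn_binned_pairs")
}

#' @export
print.scn_binned_pairs <- function(x, ...) {
  cat(sprintf("<scn_binned_pairs> %d occupied bins (%d requested), %d pairs\n",
              nrow(x$bins), x$n_bins_requested, nrow(x$pairs)))
  invisible(x)
}

#' Fit the brightness-difference / phase-difference linear model
#'
#' Ordinary least squares of Delta I on Delta phi over the ordered pair set.
#' Because the pair set is a deterministic symmetrization of the per-bin
#' values (the pair-level OLS slope is algebraically the bin-level OLS
#' slope, and the intercept is forced to zero by antisymmetry), inference
#' (standard error, p-value, confidence interval, R^2) is computed from the
#' bin-level regression with `#bins - 2` degrees of freedom; pair-level
#' degrees of freedom would overstate the information by a factor of about
#' the bin count.
#'
#' @param pairs an `scn_binned_pairs` from [preprocess_bins()] or
#'   [binned_pair_set()].
#' @param weight_by_occupancy if `TRUE`, weight bins by occupancy in the
#'   bin-level fit (the default, `FALSE`, is the unweighted fit).
#' @return an object of class `scn_delta_model` with `slope_fit`,
#'   `intercept`, `r_squared`, `se_slope`, `sigma` (residual sd, z-scored
#'   intensity units), `sigma_hours` (residual sd divided by |slope|),
#'   `p_value`, `ci` (95% for the slope), `df`.
#' @export
fit_delta_model <- function(pairs, weight_by_occupancy = FALSE) {
  stopifnot(inherits(pairs, "scn_binned_pairs"))
  pr <- pairs$pairs
  if (length(unique(pr$d_phase)) < 2)
    stop_scn("need at least 2 distinct phase differences",
             class = "scn_degenerate_error")
  if (sd(pr$d_phase) == 0)
    stop_scn("rank-deficient design: all phase differences equal",
             class = "scn_degenerate_error")
  # Pair-level fit: slope identical to bin-level; intercept ~ 0 by symmetry.
  fit_pairs <- lm(d_intensity ~ d_phase, data = pr)
  slope <- unname(coef(fit_pairs)["d_phase"])
  intercept <- unname(coef(fit_pairs)["(Intercept)"])

  b <- pairs$bins
  w <- if (weight_by_occupancy) b$n else NULL
  fit_bins <- lm(center ~ mean_phase, data = b, weights = w)
  sm <- summary(fit_bins)
  # Heteroskedasticity-consistent SE: per-bin mean-phase noise scales with
  # 1/sqrt(occupancy), so sparsely occupied tail bins are both high-leverage
  # and high-variance; the homoskedastic OLS SE is anti-conservative there.
  se <- sqrt(sandwich::vcovHC(fit_bins, type = "HC3")["mean_phase",
                                                     "mean_phase"])
  df <- fit_bins$df.residual
  tstat <- coef(fit_bins)[["mean_phase"]] / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  ci <- coef(fit_bins)["mean_phase"] + c(-1, 1) * qt(0.975, df) * se
  r2 <- sm$r.squared
  sigma <- sqrt(mean(fit_pairs$residuals^2))
  structure(list(
    slope_fit = slope, intercept = intercept, r_squared = r2,
    se_slope = se, sigma = sigma,
    sigma_hours = if (slope != 0) sigma / abs(slope) else NA_real_,
    p_value = p, ci = unname(ci), df = df,
    n_bins = nrow(b), n_pairs = nrow(pr), hour = NA_integer_
  ), class = "scn_delta_model")
}

#' @export
print.scn_delta_model <- function(x, ...) {
  cat(sprintf(
    paste0("<scn_delta_model>%s slope = %.4f (95%% CI %.4f..%.4f), ",
           "c = %.2e, R^2 = %.3f, sigma = %.3f h, p = %.3g\n"),
    if (is.na(x$hour)) "" else sprintf(" hour %d:", x$hour),
    x$slope_fit, x$ci[1], x$ci[2], x$intercept, x$r_squared,
    x$sigma_hours, x$p_value
  ))
  invisible(x)
}

#' Hourly model scan from the trough
#'
#' Fits one brightness/phase model per hour over a 24-hour period starting at
#' the trough of the overall oscillation (CT0000): the frame at trough + t
#' within the first 48 h, for t = 0..23. Per-hour failures (e.g. degenerate
#' frames) are flagged, not raised.
#'
#' @param grid an [scn_grid()].
#' @param field optional precomputed normalized `scn_circadian_field`.
#' @param n_bins,trim passed to [preprocess_bins()].
#' @return an object of class `scn_hour_scan`: a `data.frame` `scan` with one
#'   row per hour (`hour`, `frame`, `slope`, `intercept`, `r_squared`,
#'   `se_slope`, `sigma_hours`, `p_value`, `ci_lo`, `ci_hi`, `ok`), the
#'   `models` list and the `trough` hour.
#' @export
scan_hours <- function(grid, field = NULL, n_bins = 400, trim = 0.1) {
  stopifnot(inherits(grid, "scn_grid"))
  if (is.null(field))
    field <- normalize_phases(circadian_component(grid), grid)
  trough <- find_trough(grid)
  hours <- 0:23
  models <- vector("list", 24)
  rows <- lapply(hours, function(t) {
    frame_idx <- trough + t + 1L  # 1-based frame index within the first 48 h
    res <- tryCatch({
      bp <- preprocess_bins(grid$intensity[, , frame_idx], field,
                            n_bins = n_bins, trim = trim)
      m <- fit_delta_model(bp)
      m$hour <- t
      models[[t + 1L]] <<- m
      data.frame(hour = t, frame = frame_idx, slope = m$slope_fit,
                 intercept = m$intercept, r_squared = m$r_squared,
                 se_slope = m$se_slope, sigma_hours = m$sigma_hours,
                 p_value = m$p_value, ci_lo = m$ci[1], ci_hi = m$ci[2],
                 ok = TRUE)
    }, error = function(e) {
      data.frame(hour = t, frame = frame_idx, slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 se_slope = NA_real_, sigma_hours = NA_real_,
                 p_value = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 ok = FALSE)
    })
    res
  })
  structure(list(scan = do.call(rbind, rows), models = models,
                 trough = trough),
            class = "scn_hour_scan")
}

#' @export
print.scn_hour_scan <- function(x, ...) {
  best <- x$scan$hour[which.max(x$scan$r_squared)]
  cat(sprintf("<scn_hour_scan> trough at frame %d; best R^2 = %.3f at t = %d h\n",
              x$trough, max(x$scan$r_squared, na.rm = TRUE), best))
  invisible(x)
}
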