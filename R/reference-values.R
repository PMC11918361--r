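# Published reference values used as worked-example inputs.

#' Order parameters of the six slice time-series samples
#'
#' The synchronization level at CT1900, as measured by the order parameter,
#' of the six SCN slice time-series samples (two per orientation) used to
#' build and calibrate the brightness-to-phase model. Their mean (0.8358)
#' motivates the representative calibration targets of 0.8-0.84.
#'
#' @format a numeric vector of length 6.
#' @export
slice_order_parameters <- c(0.7581, 0.7699, 0.8090, 0.8442, 0.9146, 0.9193)
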