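# Domain containers: slice time-series grids and snapshot neuron tables.

SLICE_ORIENTATIONS <- c("coronal", "sagittal", "horizontal")

#' Slice time-series grid
#'
#' Container for an hourly bioluminescence movie of one SCN slice: a
#' `n_rows x n_cols x n_frames` array of nonnegative brightness values
#' (arbitrary units), a logical in-tissue mask, the frame interval in hours
#' and the slice orientation.
#'
#' @param intensity numeric 3-d array `[rows, cols, frames]`; all values must
#'   be finite.
#' @param mask logical matrix of in-tissue pixels, same spatial shape as
#'   `intensity`; must contain at least one `TRUE` pixel.
#' @param frame_interval hours between frames (default 1).
#' @param orientation one of `"coronal"`, `"sagittal"`, `"horizontal"`, or
#'   `NA` when unknown.
#' @return an object of class `scn_grid`.
#' @seealso [read_timeseries()], [synth_slice_timeseries()]
#' @export
scn_grid <- function(intensity, mask = NULL, frame_interval = 1,
                     orientation = NA_character_) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop_scn("`intensity` must be a 3-d array [rows, cols, frames]",
             class = "scn_format_error")
  if (!all(is.finite(intensity)))
    stop_scn("intensities must all be finite", class = "scn_format_error")
  dm <- dim(intensity)
  if (dm[3] < 48L)
    stop_scn("insufficient data: need >= 48 frames, got ", dm[3],
             class = "scn_insufficient_data_error")
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dm[1:2]))
    stop_scn("mask shape must match the spatial shape of `intensity`",
             class = "scn_format_error")
  if (!any(mask))
    stop_scn("empty mask: no in-tissue pixels", class = "scn_empty_mask_error")
  if (!is.na(orientation))
    orientation <- match.arg(orientation, SLICE_ORIENTATIONS)
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  structure(
    list(intensity = intensity, mask = mask,
         frame_interval = frame_interval, orientation = orientation),
    class = "scn_grid"
  )
}

#' @export
print.scn_grid <- function(x, ...) {
  dm <- dim(x$intensity)
  cat(sprintf(
    "<scn_grid> %d x %d pixels, %d frames (%g h apart), %d in-tissue pixels%s\n",
    dm[1], dm[2], dm[3], x$frame_interval, sum(x$mask),
    if (is.na(x$orientation)) "" else paste0(", ", x$orientation)
  ))
  invisible(x)
}

#' @export
dim.scn_grid <- function(x) dim(x$intensity)

# Number of frames and the masked pixel series as a matrix (pixels x frames).
n_frames <- function(grid) dim(grid$intensity)[3]

masked_series <- function(grid) {
  dm <- dim(grid$intensity)
  m <- matrix(grid$intensity, dm[1] * dm[2], dm[3])
  m[as.vector(grid$mask), , drop = FALSE]
}

# Spatial mean over in-tissue pixels at each frame.
tissue_mean_series <- function(grid) colMeans(masked_series(grid))

#' Snapshot neuron table
#'
#' A table of PER2-expressing neurons detected in a cleared whole-mount SCN:
#' one row per neuron with its 3D position in micrometres and a scalar
#' intensity (median spot brightness). Axis convention: `x_um` medial-lateral,
#' `y_um` rostral-caudal, `z_um` dorsal-ventral; virtual coronal slabs are cut
#' on y, sagittal on x, horizontal on z.
#'
#' @param neuron_id integer ids, unique.
#' @param x_um,y_um,z_um coordinates in micrometres, finite.
#' @param intensity nonnegative scalar brightness per neuron.
#' @return a `data.frame` of class `scn_neuron_table`.
#' @seealso [read_neuron_table()], [synth_snapshot()], [virtual_slice()]
#' @export
scn_neuron_table <- function(neuron_id, x_um, y_um, z_um, intensity) {
  neuron_id <- as.integer(neuron_id)
  if (anyDuplicated(neuron_id))
    stop_scn("duplicate neuron ids", class = "scn_format_error")
  coords <- cbind(x_um, y_um, z_um)
  if (length(neuron_id) > 0 && !all(is.finite(coords)))
    stop_scn("coordinates must be finite", class = "scn_format_error")
  if (length(neuron_id) > 0 &&
      (!all(is.finite(intensity)) || any(intensity < 0)))
    stop_scn("intensities must be finite and nonnegative",
             class = "scn_format_error")
  out <- data.frame(neuron_id = neuron_id,
                    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                    z_um = as.numeric(z_um),
                    intensity = as.numeric(intensity))
  class(out) <- c("scn_neuron_table", "data.frame")
  out
}

#' @export
print.scn_neuron_table <- function(x, ...) {
  cat(sprintf("<scn_neuron_table> %d neurons\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

neuron_coords <- function(table) {
  as.matrix(as.data.frame(table)[, c("x_um", "y_um", "z_um")])
}
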