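# Readers and writers: frame-stack text movies, optional TIFF stacks,
# CSV neuron tables. All writers are full-precision (%.17g) so that
# write -> read round-trips are exact.

NEURON_TABLE_HEADER <- c("neuron_id", "x_um", "y_um", "z_um", "intensity")

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a slice time-series movie
#'
#' Reads a movie either from the package's stacked text format (frames as
#' whitespace-separated matrices separated by blank lines, with `#` comment
#' headers) or from a multi-page grayscale TIFF (requires the `tiff` package).
#' The in-tissue mask is read from `mask_path` when given, otherwise inferred:
#' a pixel is in-tissue if its temporal mean intensity exceeds `mask_floor`.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"text"` or `"tiff"`.
#' @param mask_path optional text file with a 0/1 matrix of the same spatial
#'   shape.
#' @param mask_floor threshold on the temporal mean used when inferring the
#'   mask (default 0; the movie pixel scale is instrument-specific so no fixed
#'   criterion is imposed).
#' @param frame_interval hours between frames (default 1).
#' @param orientation slice orientation label, or `NA`.
#' @return an [scn_grid()].
#' @export
read_timeseries <- function(path, format = c("auto", "text", "tiff"),
                            mask_path = NULL, mask_floor = 0,
                            frame_interval = 1, orientation = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_scn("file not found: ", path, class = "scn_io_error")
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  arr <- switch(format,
    text = read_frame_stack_text(path),
    tiff = read_frame_stack_tiff(path)
  )
  mask <- if (!is.null(mask_path)) {
    m <- as.matrix(read.table(mask_path))
    dimnames(m) <- NULL
    if (!identical(dim(m), dim(arr)[1:2]))
      stop_scn("mask shape does not match the frames", class = "scn_format_error")
    m > 0
  } else {
    apply(arr, c(1, 2), mean) > mask_floor
  }
  if (!any(mask))
    stop_scn("empty mask: no pixel exceeds the mask floor",
             class = "scn_empty_mask_error")
  scn_grid(arr, mask = mask, frame_interval = frame_interval,
           orientation = orientation)
}

read_frame_stack_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(c(TRUE, diff(blank) == -1))[!blank]
  frames <- split(lines[!blank], grp)
  mats <- lapply(frames, function(fl) {
    rows <- lapply(strsplit(trimws(fl), "\\s+"), as.numeric)
    ncol <- unique(lengths(rows))
    if (length(ncol) != 1L)
      stop_scn("ragged frame: rows have differing lengths",
               class = "scn_format_error")
    do.call(rbind, rows)
  })
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L)
    stop_scn("ragged frames: frames have differing shapes",
             class = "scn_format_error")
  if (length(mats) < 48L)
    stop_scn("insufficient data: need >= 48 frames, got ", length(mats),
             class = "scn_insufficient_data_error")
  arr <- array(NA_real_, c(dims[[1]], length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  if (anyNA(arr))
    stop_scn("non-numeric values in frame stack", class = "scn_format_error")
  arr
}

read_frame_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_scn("reading TIFF stacks requires the 'tiff' package",
             class = "scn_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse any channel axis
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop_scn("ragged frames: TIFF pages have differing shapes",
             class = "scn_format_error")
  if (length(pages) < 48L)
    stop_scn("insufficient data: need >= 48 frames, got ", length(pages),
             class = "scn_insufficient_data_error")
  arr <- array(NA_real_, c(dims[[1]], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Write a slice time-series movie in the stacked text format
#'
#' One whitespace-separated matrix per frame, frames separated by blank
#' lines, preceded by `#` comment headers recording the shape, frame interval
#' and orientation. Inverse of [read_timeseries()] (text format).
#'
#' @param grid an [scn_grid()].
#' @param path output file.
#' @param mask_path optional path for a 0/1 mask sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(grid, path, mask_path = NULL) {
  stopifnot(inherits(grid, "scn_grid"))
  dm <- dim(grid$intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# scn-frames %d %d %d", dm[1], dm[2], dm[3]),
    sprintf("# frame_interval_hours %g", grid$frame_interval),
    sprintf("# orientation %s", grid$orientation)
  ), con)
  for (t in seq_len(dm[3])) {
    writeLines(apply(grid$intensity[, , t, drop = FALSE], 1,
                     function(r) paste(fmt_num(r), collapse = " ")), con)
    writeLines("", con)
  }
  if (!is.null(mask_path))
    writeLines(apply(grid$mask, 1,
                     function(r) paste(as.integer(r), collapse = " ")),
               mask_path)
  invisible(path)
}

#' Read a snapshot neuron table from delimited text
#'
#' Expects a comma-delimited file with a header naming at least the columns
#' `neuron_id, x_um, y_um, z_um, intensity` (any order; extra columns are
#' ignored).
#'
#' @param path CSV file.
#' @return an [scn_neuron_table()].
#' @export
read_neuron_table <- function(path) {
  if (!file.exists(path))
    stop_scn("file not found: ", path, class = "scn_io_error")
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(NEURON_TABLE_HEADER, names(df))
  if (length(missing) > 0)
    stop_scn("missing column ", paste(missing, collapse = ", "),
             class = "scn_format_error")
  scn_neuron_table(df$neuron_id, df$x_um, df$y_um, df$z_um, df$intensity)
}

#' Write a snapshot neuron table as CSV
#'
#' Fixed header `neuron_id,x_um,y_um,z_um,intensity`; numeric fields at full
#' precision so [read_neuron_table()] is an exact inverse.
#'
#' @param table an [scn_neuron_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_neuron_table <- function(table, path) {
  stopifnot(inherits(table, "scn_neuron_table"))
  lines <- paste(NEURON_TABLE_HEADER, collapse = ",")
  if (nrow(table) > 0) {
    lines <- c(lines, paste(
      table$neuron_id, fmt_num(table$x_um), fmt_num(table$y_um),
      fmt_num(table$z_um), fmt_num(table$intensity), sep = ","
    ))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_scn("cannot write to ", path, class = "scn_io_error")
  invisible(path)
}

#' Write a ground-truth sidecar table as CSV
#'
#' Ground truth from the synthetic generators, keyed by pixel (row, col) or
#' neuron id, written at full precision.
#'
#' @param truth a `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  num <- vapply(truth, is.double, logical(1))
  out <- truth
  out[num] <- lapply(truth[num], fmt_num)
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
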