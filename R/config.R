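# Run configuration: defaults for every stage parameter, YAML override,
# config hashing and the plain-text run log.

#' Default run configuration
#'
#' One flat list of every stage parameter, with the defaults used throughout
#' the analyses: 400 intensity bins with 10% trimming for the delta-model
#' preprocessing, order-parameter calibration target 0.8, 20 um connection
#' radius, 100 um virtual slab width, a 4 x 4 sweep grid with q log-spaced
#' over [1e-4, 1e-1] and K linear over [0, 2], 30 s integration step and 24 h
#' simulated duration.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `scn_config`.
#' @export
scn_config <- function(...) {
  defaults <- list(
    seed = 1L,
    mask_floor = 0,
    n_bins = 400L,
    trim = 0.1,
    k_clusters = 5L,
    hist_bin_width = 0.5,
    calibration_target = 0.8,
    connection_radius = 20,
    slab_width = 100,
    q_grid = 10^seq(-4, -2, length.out = 4),
    K_grid = seq(0, 2, length.out = 4),
    dt_seconds = 30,
    duration_hours = 24,
    direction_bins = 35L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop_scn("unknown config parameter(s): ", paste(unknown, collapse = ", "),
             class = "scn_config_error")
  cfg <- modifyList(defaults, over)
  class(cfg) <- c("scn_config", "list")
  cfg
}

#' Read a configuration from a YAML-style key-value file
#'
#' Values present in the file override the [scn_config()] defaults.
#'
#' @param path YAML file.
#' @return an `scn_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scn_config, vals %||% list())
}

#' @rdname read_config
#' @param config an `scn_config` list to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; recorded in run logs so that
#' identical config + seed can be recognised as reproducing identical outputs.
#'
#' @param config an `scn_config` list.
#' @return a hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Append a stage record to a plain-text run log
#'
#' Each record carries the stage name, seed, config hash, every parameter
#' value and the paths of the stage outputs.
#'
#' @param log_path log file (created if absent).
#' @param stage stage name, e.g. a CLI subcommand.
#' @param config an `scn_config` list.
#' @param outputs character vector of output paths.
#' @return `log_path`, invisibly.
#' @export
write_run_log <- function(log_path, stage, config, outputs = character()) {
  fmt_val <- function(v) paste(format(v, digits = 15), collapse = ", ")
  lines <- c(
    sprintf("[%s] stage: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage),
    sprintf("  seed: %s", fmt_val(config$seed)),
    sprintf("  config_hash: %s", config_hash(config)),
    vapply(names(config), function(n) sprintf("  param %s: %s", n, fmt_val(config[[n]])),
           character(1)),
    sprintf("  output: %s", outputs),
    ""
  )
  cat(lines, file = log_path, sep = "\n", append = TRUE)
  invisible(log_path)
}
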