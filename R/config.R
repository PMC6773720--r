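#' Pipeline run configuration
#'
#' Collects every tunable constant of the preprocessing and timing pipeline
#' with its default: tracker confidence threshold 0.9; display bounds
#' x in \[0, 1\], y in \[-0.3, 1\] (surface units); Gaussian smoothing sigma
#' 3 samples; velocity lag 9 and acceleration lag 5 samples; saccade
#' thresholds 300 m/s^2 and 1.5 x target speed with merge gap 2 and minimum
#' duration 2 samples; tracker rate 200 Hz; response-outlier threshold
#' 0.5 s; projector system delay 0.049259 s; gain-eligibility mask padding
#' 12 samples (see [compute_gain()]); gain-window fallback start 0.2 s for
#' trials whose catch-up saccade is not on record (e.g. gaze entered the
#' display late). All overridable.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `run_config`.
#' @examples
#' run_config(smooth_sigma = 5)$smooth_sigma
#' @export
run_config <- function(...) {
  cfg <- list(
    conf_min = 0.9,
    x_bounds = c(0, 1),
    y_bounds = c(-0.3, 1),
    smooth_sigma = 3,
    vel_lag = 9,
    acc_lag = 5,
    acc_threshold = 300,
    vel_ratio = 1.5,
    merge_gap = 2,
    min_dur = 2,
    rate = 200,
    gap_factor = 3,
    gain_mask_pad = 12,
    fallback_start = 0.2,
    error_exclusion = 0.5,
    system_delay = 0.049259)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Read and write gaze-sample tables
#'
#' Delimited text (comma-separated, '.' decimal, header row) with columns
#' `trial_id, t, x_surf, y_surf, confidence`. Empty fields become NA and are
#' counted as missing downstream. Reading fails naming any absent required
#' column; unknown extra columns are kept with a warning.
#'
#' @param path file path.
#' @return data.frame of gaze samples.
#' @export
read_gaze_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "t", "x_surf", "y_surf", "confidence")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("gaze table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tab), required)
  if (length(extra)) warning("ignoring unknown column(s): ",
                             paste(extra, collapse = ", "))
  tab
}

#' @rdname read_gaze_table
#' @param x data.frame to write.
#' @export
write_gaze_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write generic result tables
#'
#' Thin CSV round-trip helpers used for trial plans, per-trial summaries and
#' cohort datasets; lossless for finite values.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_table_file` returns a data.frame; `write_table_file`
#'   returns `path` invisibly.
#' @export
write_table_file <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
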