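#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline in one validated
#' list.  Defaults follow the published procedure where it states a
#' value (19 px unit areas slid every 10 px, 30 Hz resampling, 90 %
#' cumulative amplitude-ratio cutoff); the remaining defaults are this
#' package's documented choices.
#'
#' @param unit_size side of the square unit area, pixels.
#' @param stride sliding step between unit-area anchors, pixels.
#' @param cutoff cumulative amplitude-ratio value at which the ROI
#'   bottom is fixed, in (0, 1].
#' @param arm_width_fraction margin trimmed inside each shoulder, as a
#'   fraction of the shoulder-to-shoulder pixel distance.
#' @param sample_rate_hz uniform resampling rate of the depth signal.
#' @param window_s moving-average smoothing window, seconds.
#' @param min_interval_s minimum peak-to-peak spacing accepted by the
#'   breath detector, seconds (1.5 s bounds RR at 40 breaths/min).
#' @param min_prominence_mm peak prominence threshold for the depth
#'   signal, mm; `NULL` selects the adaptive rule
#'   `max(0.5, 0.2 * median excursion)`.
#' @param min_prominence_L prominence threshold for the reference volume
#'   trace, litres; `NULL` selects `max(0.05, 0.2 * median excursion)`.
#' @param match_window_s maximum peak-time offset when pairing estimated
#'   and reference breaths, seconds.
#' @param max_subject_depth_mm foreground segmentation threshold: pixels
#'   at or beyond this depth are background.
#' @param alpha significance level of the Bland-Altman bias tests.
#' @param rr_error_threshold_bpm per-breath RR difference above which a
#'   breath counts as an RR error (strictly greater than).
#' @param intercept logical; include an intercept in the calibration
#'   regression.
#'
#' @return A named list of class `resp_config`.
#' @export
resp_config <- function(unit_size = 19L,
                        stride = 10L,
                        cutoff = 0.90,
                        arm_width_fraction = 0.15,
                        sample_rate_hz = 30,
                        window_s = 0.5,
                        min_interval_s = 1.5,
                        min_prominence_mm = NULL,
                        min_prominence_L = NULL,
                        match_window_s = 2.0,
                        max_subject_depth_mm = 2000,
                        alpha = 0.05,
                        rr_error_threshold_bpm = 1.0,
                        intercept = TRUE) {
  cfg <- list(
    unit_size = as.integer(unit_size),
    stride = as.integer(stride),
    cutoff = cutoff,
    arm_width_fraction = arm_width_fraction,
    sample_rate_hz = sample_rate_hz,
    window_s = window_s,
    min_interval_s = min_interval_s,
    min_prominence_mm = min_prominence_mm,
    min_prominence_L = min_prominence_L,
    match_window_s = match_window_s,
    max_subject_depth_mm = max_subject_depth_mm,
    alpha = alpha,
    rr_error_threshold_bpm = rr_error_threshold_bpm,
    intercept = isTRUE(intercept)
  )
  validate_config(cfg)
  class(cfg) <- "resp_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot_scalar_number(cfg$unit_size, "unit_size", min = 1)
  stopifnot_scalar_number(cfg$stride, "stride", min = 1)
  if (cfg$unit_size < cfg$stride)
    abort_respdepth("validation", "`unit_size` must be >= `stride`")
  stopifnot_scalar_number(cfg$cutoff, "cutoff", min = 0, max = 1,
                          strict_min = TRUE)
  stopifnot_scalar_number(cfg$arm_width_fraction, "arm_width_fraction",
                          min = 0, max = 0.49)
  stopifnot_scalar_number(cfg$sample_rate_hz, "sample_rate_hz", min = 1)
  stopifnot_scalar_number(cfg$window_s, "window_s", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(cfg$min_interval_s, "min_interval_s", min = 0)
  if (!is.null(cfg$min_prominence_mm))
    stopifnot_scalar_number(cfg$min_prominence_mm, "min_prominence_mm", min = 0)
  if (!is.null(cfg$min_prominence_L))
    stopifnot_scalar_number(cfg$min_prominence_L, "min_prominence_L", min = 0)
  stopifnot_scalar_number(cfg$match_window_s, "match_window_s", min = 0)
  stopifnot_scalar_number(cfg$max_subject_depth_mm, "max_subject_depth_mm",
                          min = 0, strict_min = TRUE)
  stopifnot_scalar_number(cfg$alpha, "alpha", min = 0, max = 1,
                          strict_min = TRUE)
  stopifnot_scalar_number(cfg$rr_error_threshold_bpm, "rr_error_threshold_bpm",
                          min = 0)
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected rather than silently ignored, so that a
#' typo in a config file cannot leave a default in force unnoticed.
#'
#' @param path YAML file with any subset of the [resp_config()] keys.
#' @param ... overrides applied after the file is read.
#' @return A `resp_config` list.
#' @export
resp_config_from_yaml <- function(path, ...) {
  if (!file.exists(path))
    abort_respdepth("format", sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(resp_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    abort_respdepth("validation",
                    paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  do.call(resp_config, vals)
}

#' @export
print.resp_config <- function(x, ...) {
  cat("respdepth pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(v)) "(adaptive)" else format(v)))
  }
  invisible(x)
}
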