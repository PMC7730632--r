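#' End-to-end breath estimation from a depth sequence
#'
#' Runs the full chain on one recording: foreground landmarks on the
#' initial frame, tentative ROI from the shoulders, unit-area waveforms,
#' per-row amplitude ratios, final ROI at the cumulative-ratio cutoff,
#' ROI-mean signal, smoothing, and breath segmentation.  The ROI is
#' determined once, from the initial frame and the full recording, and
#' reused; there is no frame-by-frame update.
#'
#' @param seq a [depth_sequence()].
#' @param config a [resp_config()].
#' @param calibration optional [fit_calibration()] model; when given,
#'   per-breath tidal volumes are added to the breath table.
#' @return Object of class `resp_estimate`: landmarks, both ROIs, the
#'   row amplitude-ratio profile, the smoothed signal, the breath
#'   events, and a per-breath table `breaths` with `peak_time_s`,
#'   `amplitude_mm`, `rr_bpm` (NA for the first breath) and `tv_L` when
#'   calibrated.
#' @export
run_estimate <- function(seq, config = resp_config(), calibration = NULL) {
  if (!inherits(seq, "depth_sequence"))
    abort_respdepth("validation", "`seq` must be a depth_sequence")
  frame1 <- seq$frames[, , 1]
  mask <- segment_foreground(frame1, config$max_subject_depth_mm)
  box <- detect_upper_body(frame1, max_subject_depth_mm =
                             config$max_subject_depth_mm)
  shoulders <- detect_shoulders(mask, box)

  arm_px <- round(config$arm_width_fraction *
                    (shoulders$right[2] - shoulders$left[2]))
  tentative <- build_tentative_roi(shoulders, seq$height, seq$width, arm_px)
  grid <- build_unit_grid(tentative, config$unit_size, config$stride)
  units <- extract_unit_waveforms(seq, grid, config$sample_rate_hz)

  sig_tent <- roi_mean_signal(seq, tentative, config$sample_rate_hz)
  sm_tent <- resp_smooth(sig_tent, config$window_s)
  ev_tent <- detect_breaths(sm_tent, config$min_interval_s,
                            config$min_prominence_mm)
  windows <- breath_windows(ev_tent, length(sm_tent$x))
  rows <- compute_row_waveforms(units, windows, config$window_s)
  final <- finalize_roi(tentative, rows, grid, config$cutoff)

  sig <- roi_mean_signal(seq, final, config$sample_rate_hz)
  sm <- resp_smooth(sig, config$window_s)
  ev <- detect_breaths(sm, config$min_interval_s, config$min_prominence_mm)

  breaths <- data.frame(
    peak_time_s = ev$peak_times_s,
    amplitude_mm = ev$amplitudes,
    rr_bpm = c(NA_real_, if (length(ev$peaks) > 1) 60 / ev$intervals)
  )
  if (!is.null(calibration))
    breaths$tv_L <- as.numeric(estimate_tv(calibration, breaths$amplitude_mm))

  structure(list(shoulders = shoulders, body_box = box,
                 roi_tentative = tentative, roi_final = final,
                 row_profile = data.frame(
                   grid_row = rows$row_index,
                   amplitude_mm = rows$row_amplitude,
                   amplitude_ratio = rows$amplitude_ratio,
                   cumulative_ratio = rows$cumulative_ratio),
                 signal = sm, events = ev, breaths = breaths,
                 config = config),
            class = "resp_estimate")
}

#' @export
print.resp_estimate <- function(x, ...) {
  cat("respdepth estimate\n")
  cat(sprintf("  shoulders: left (%d, %d), right (%d, %d)\n",
              x$shoulders$left[1], x$shoulders$left[2],
              x$shoulders$right[1], x$shoulders$right[2]))
  cat(sprintf("  ROI: rows [%d, %d), cols [%d, %d) (tentative bottom %d)\n",
              x$roi_final$top, x$roi_final$bottom,
              x$roi_final$left, x$roi_final$right, x$roi_tentative$bottom))
  cat(sprintf("  breaths: %d, mean amplitude %.2f mm, mean RR %.2f BPM\n",
              nrow(x$breaths), mean(x$breaths$amplitude_mm),
              mean(x$breaths$rr_bpm, na.rm = TRUE)))
  invisible(x)
}

#' Segment a reference volume trace into breaths
#'
#' The reference trace is processed the same way as the depth signal:
#' resampled onto a uniform grid, smoothed with the same window, and
#' segmented with the same prominence-based detector (thresholds in
#' litres).  Times are moved onto the depth clock using the trigger
#' offset, so the result is directly matchable against a
#' [run_estimate()] breath table.
#'
#' @param ref a [reference_trace()].
#' @param offset trigger offset from [align_by_trigger()], seconds.
#' @param config a [resp_config()].
#' @return List with `breaths` (`peak_time_s` on the depth clock,
#'   `tv_L`, `rr_bpm`), `events`, `signal`.
#' @export
segment_reference <- function(ref, offset, config = resp_config()) {
  rate <- 1 / median(diff(ref$time_s))
  tgrid <- uniform_time_grid(ref$time_s, rate)
  v <- approx(ref$time_s, ref$volume_L, xout = tgrid, rule = 2)$y
  sig <- resp_signal(tgrid - offset, v, rate)
  # resp_signal checks uniformity; volume stays in litres, unshifted
  sm <- resp_smooth(sig, config$window_s)
  ev <- detect_breaths(sm, config$min_interval_s,
                       min_prominence = config$min_prominence_L,
                       prominence_floor = 0.05)
  breaths <- data.frame(
    peak_time_s = ev$peak_times_s,
    tv_L = ev$amplitudes,
    rr_bpm = c(NA_real_, if (length(ev$peaks) > 1) 60 / ev$intervals)
  )
  list(breaths = breaths, events = ev, signal = sm)
}

#' Calibrate tidal volume against a reference recording
#'
#' Aligns the reference trace with the depth recording through the
#' trigger channel, segments both signals with the same breath
#' detector, pairs breaths by peak time, and fits the single linear
#' regression of reference tidal volume on depth amplitude.
#'
#' @param seq a [depth_sequence()] (or a pre-computed `resp_estimate`).
#' @param ref the synchronous [reference_trace()].
#' @param config a [resp_config()].
#' @param label stratum label stored with the model.
#' @return A [fit_calibration()] model with attributes `pairs` (the
#'   matched training breaths) and `offset` (trigger offset, s).
#' @export
run_calibrate <- function(seq, ref, config = resp_config(),
                          label = "pooled") {
  est <- if (inherits(seq, "resp_estimate")) seq
         else run_estimate(seq, config)
  offset <- align_by_trigger(seq, ref)
  refseg <- segment_reference(ref, offset, config)
  pairs <- match_breaths(
    list(peak_time_s = est$breaths$peak_time_s,
         tv_L = est$breaths$amplitude_mm),   # amplitudes ride the tv slot
    list(peak_time_s = refseg$breaths$peak_time_s,
         tv_L = refseg$breaths$tv_L),
    window_s = config$match_window_s)
  if (nrow(pairs) < 2L)
    abort_respdepth("fit", "fewer than 2 matched breaths for calibration")
  model <- fit_calibration(pairs$est_tv_L, pairs$ref_tv_L, label = label,
                           intercept = config$intercept)
  attr(model, "pairs") <- pairs
  attr(model, "offset") <- offset
  model
}

#' Evaluate agreement between estimated and reference breaths
#'
#' Pairs the two breath tables by peak time and computes the agreement
#' statistics: TV mean absolute relative error, Bland-Altman fixed and
#' proportional bias, and the RR error count.
#'
#' @param est_breaths data.frame with `peak_time_s`, `tv_L`, `rr_bpm`
#'   (e.g. `run_estimate(..., calibration = m)$breaths`).
#' @param ref_breaths data.frame with the same columns on the same
#'   clock (e.g. `segment_reference(...)$breaths`).
#' @param config a [resp_config()].
#' @return An [agreement_report()] with attribute `pairs`.
#' @export
run_evaluate <- function(est_breaths, ref_breaths, config = resp_config()) {
  for (nm in c("peak_time_s", "tv_L"))
    if (is.null(est_breaths[[nm]]) || is.null(ref_breaths[[nm]]))
      abort_respdepth("evaluation",
                      sprintf("breath tables need a `%s` column", nm))
  pairs <- match_breaths(est_breaths, ref_breaths,
                         window_s = config$match_window_s)
  rep <- agreement_report(pairs, alpha = config$alpha,
                          rr_threshold_bpm = config$rr_error_threshold_bpm)
  attr(rep, "pairs") <- pairs
  rep
}
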