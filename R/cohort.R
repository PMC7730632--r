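#' Run a calibration-validation study over a synthetic cohort
#'
#' For every subject preset the quiet and deep recordings are rendered,
#' the pipeline is run on each, and estimated breaths are paired with
#' the subject's reference trace.  Within each stratum the pooled
#' breath pairs are split alternately (odd breaths train, even breaths
#' held out), a single regression is fitted on the training half, and
#' the held-out half is predicted, so the reported error is out of
#' sample while every subject contributes to both halves.
#'
#' @param cohort list of presets from [make_cohort()].
#' @param config a [resp_config()].
#' @param fps rendering frame rate (default 15; the pipeline resamples
#'   to `config$sample_rate_hz` regardless).
#' @param trigger_lag_s reference-recording head start, seconds.
#' @return List with `pairs` (one row per matched breath: subject,
#'   stratum, pattern, amplitude, reference TV, RR pair, train flag,
#'   held-out TV estimate), `models` (per-stratum [fit_calibration()]
#'   fits), `summary` (held-out MARE overall and per stratum, RR error
#'   count).
#' @export
run_cohort <- function(cohort, config = resp_config(), fps = 15,
                       trigger_lag_s = 1.0) {
  rows <- list()
  for (subj in cohort) {
    for (pat in c("normal", "deep")) {
      prog <- if (pat == "normal") subj$program_normal else subj$program_deep
      rend <- render_sequence(subj$scene, prog, subj$noise, fps = fps)
      ref <- synth_reference_trace(rend$truth, sample_rate = 100,
                                   trigger_lag_s = trigger_lag_s)
      est <- run_estimate(rend$seq, config)
      offset <- align_by_trigger(rend$seq, ref)
      refseg <- segment_reference(ref, offset, config)
      pr <- match_breaths(
        list(peak_time_s = est$breaths$peak_time_s,
             tv_L = est$breaths$amplitude_mm,
             rr_bpm = est$breaths$rr_bpm),
        list(peak_time_s = refseg$breaths$peak_time_s,
             tv_L = refseg$breaths$tv_L,
             rr_bpm = refseg$breaths$rr_bpm),
        window_s = config$match_window_s)
      if (nrow(pr) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$id, stratum = subj$stratum, pattern = pat,
        amplitude_mm = pr$est_tv_L, ref_tv_L = pr$ref_tv_L,
        est_rr_bpm = pr$est_rr_bpm, ref_rr_bpm = pr$ref_rr_bpm,
        peak_time_s = est$breaths$peak_time_s[pr$est_idx])
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 4L)
    abort_respdepth("evaluation", "cohort produced too few matched breaths")

  # alternate split within each subject x pattern recording
  pairs$train <- FALSE
  for (ii in split(seq_len(nrow(pairs)),
                   paste(pairs$subject, pairs$pattern))) {
    pairs$train[ii] <- seq_along(ii) %% 2L == 1L
  }

  models <- list()
  pairs$est_tv_L <- NA_real_
  for (st in unique(pairs$stratum)) {
    tr <- pairs$stratum == st & pairs$train
    te <- pairs$stratum == st & !pairs$train
    models[[st]] <- fit_calibration(pairs$amplitude_mm[tr],
                                    pairs$ref_tv_L[tr], label = st,
                                    intercept = config$intercept)
    pairs$est_tv_L[te] <- as.numeric(
      estimate_tv(models[[st]], pairs$amplitude_mm[te]))
  }
  held <- pairs[!pairs$train, ]
  mare_all <- mean_absolute_relative_error(held$est_tv_L, held$ref_tv_L)
  mare_strat <- vapply(unique(held$stratum), function(st) {
    h <- held[held$stratum == st, ]
    mean_absolute_relative_error(h$est_tv_L, h$ref_tv_L)
  }, numeric(1))
  ok <- is.finite(pairs$est_rr_bpm) & is.finite(pairs$ref_rr_bpm)
  rr <- rr_error_count(pairs$est_rr_bpm[ok], pairs$ref_rr_bpm[ok],
                       config$rr_error_threshold_bpm)
  list(pairs = pairs, models = models,
       summary = list(mare_holdout_pct = mare_all,
                      mare_by_stratum_pct = mare_strat,
                      rr_errors = unname(rr["errors"]),
                      rr_total = unname(rr["total"]),
                      n_holdout = nrow(held)))
}
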