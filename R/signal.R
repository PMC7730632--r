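#' Respiratory displacement signal
#'
#' Uniformly sampled displacement of the ROI surface, in millimetres.
#' The sign convention is inspiration-positive: the chest moving toward
#' the camera (depth decreasing) makes `x` rise, so signal peaks are
#' end-inspiration and valleys end-expiration.  (The raw depth trace is
#' the mirror image.)
#'
#' @param t sample times, seconds, uniformly spaced.
#' @param x displacement, mm (baseline-removed).
#' @param sample_rate sampling rate, Hz.
#' @return Object of class `resp_signal`.
#' @export
resp_signal <- function(t, x, sample_rate) {
  if (length(t) != length(x))
    abort_respdepth("validation", "`t` and `x` must have equal length")
  if (any(!is.finite(x)))
    abort_respdepth("validation", "signal contains non-finite values")
  if (length(t) > 1 && max(abs(diff(t) - 1 / sample_rate)) > 1e-9)
    abort_respdepth("validation", "time grid is not uniform at sample_rate")
  structure(list(t = t, x = x, sample_rate = sample_rate),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("resp_signal: %d samples @ %g Hz, %.1f s, range [%.2f, %.2f] mm\n",
              length(x$x), x$sample_rate, diff(range(x$t)),
              min(x$x), max(x$x)))
  invisible(x)
}

#' @export
plot.resp_signal <- function(x, ...) {
  plot(x$t, x$x, type = "l", xlab = "time (s)",
       ylab = "displacement (mm)", ...)
  invisible(x)
}

#' ROI-mean respiratory signal
#'
#' Averages the valid depth pixels inside the ROI frame by frame,
#' negates (inspiration-positive), removes the mean, and linearly
#' resamples onto a uniform grid.
#'
#' @param seq a [depth_sequence()].
#' @param roi ROI rectangle (normally the final ROI).
#' @param sample_rate resampling rate, Hz (default 30).
#' @return A [resp_signal()].
#' @export
roi_mean_signal <- function(seq, roi, sample_rate = 30) {
  validate_roi(roi, seq$height, seq$width)
  rows <- (roi$top + 1L):roi$bottom
  cols <- (roi$left + 1L):roi$right
  block <- matrix(seq$frames[rows, cols, , drop = FALSE],
                  ncol = seq$n_frames)
  valid <- block > 0L
  cnt <- colSums(valid)
  if (any(cnt == 0L))
    abort_respdepth("signal",
                    sprintf("ROI fully invalid in frame %d",
                            which(cnt == 0L)[1]))
  raw <- colSums(block * valid) / cnt
  x <- -raw
  x <- x - mean(x)
  tgrid <- uniform_time_grid(seq$timestamps, sample_rate)
  xi <- approx(seq$timestamps, x, xout = tgrid, rule = 2)$y
  resp_signal(tgrid, xi - mean(xi), sample_rate)
}

#' Zero-phase moving-average smoothing
#'
#' Centred moving average over `round(window_s * rate)` samples (forced
#' odd); at the edges the window shrinks symmetrically so the output has
#' the same length and grid and constant signals pass unchanged.  A
#' 0.5 s window passes the sub-1 Hz respiratory band while suppressing
#' sensor jitter.
#'
#' @param sig a [resp_signal()].
#' @param window_s window length, seconds (default 0.5).
#' @return Smoothed [resp_signal()].
#' @export
resp_smooth <- function(sig, window_s = 0.5) {
  w <- round(window_s * sig$sample_rate)
  if (w < 1)
    abort_respdepth("validation", "smoothing window shorter than one sample")
  resp_signal(sig$t, moving_average(sig$x, w), sig$sample_rate)
}

# centred moving average over w samples (forced odd), window shrinking
# symmetrically at the edges; length-preserving, zero phase
moving_average <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  shrink <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - shrink
  hi <- seq_len(n) + shrink
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Strict local maxima of x, plateau-tolerant (centre of plateau), and
# their topographic prominences.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[j])
        peaks <- c(peaks, as.integer((i + j) %/% 2))
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a higher sample, track the minimum on the way
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { if (x[i] < lmin) lmin <- x[i]; i <- i - 1L }
    if (i < 1L && lmin == h) lmin <- min(x[1:p])
    rmin <- h
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= h) { if (x[i] < rmin) rmin <- x[i]; i <- i + 1L }
    if (i > n && rmin == h) rmin <- min(x[p:n])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Breath segmentation by peak and valley detection
#'
#' Local maxima with prominence at or above a threshold and spaced at
#' least `min_interval_s` apart are end-inspiration peaks; between
#' consecutive peaks the global minimum is the end-expiration valley,
#' and a leading valley before the first peak is included when present.
#' Only complete valley-to-peak pairs yield amplitudes, so a recording
#' starting mid-inspiration drops its first partial breath.  The
#' adaptive prominence threshold is `max(floor, 0.2 * median
#' peak-to-trough excursion)` of the signal, admitting both quiet and
#' deep breathing without tuning.
#'
#' @param sig a smoothed [resp_signal()] (or a reference volume trace
#'   expressed as one, with `prominence_floor` in litres).
#' @param min_interval_s minimum peak spacing, seconds (default 1.5,
#'   bounding the rate at 40 breaths/min).
#' @param min_prominence prominence threshold in signal units; `NULL`
#'   (default) selects the adaptive rule.
#' @param prominence_floor lower bound of the adaptive rule (default
#'   0.5, intended for mm signals; use ~0.05 for litre traces).
#' @return Object of class `breath_events`: `peaks`, `valleys` (sample
#'   indices, 1-based), `peak_times_s`, `valley_times_s`, `amplitudes`
#'   (x at peak minus x at preceding valley), `intervals` (peak-to-peak,
#'   seconds, length `length(peaks) - 1`).
#' @export
detect_breaths <- function(sig, min_interval_s = 1.5,
                           min_prominence = NULL,
                           prominence_floor = 0.5) {
  x <- sig$x
  n <- length(x)
  if (n < 2 * min_interval_s * sig$sample_rate)
    abort_respdepth("signal", "signal too short for breath detection")
  cand <- local_maxima(x)
  if (length(cand) == 0L)
    abort_respdepth("signal", "no respiration detected (no peaks)")
  prom <- peak_prominence(x, cand)
  if (is.null(min_prominence)) {
    mins <- local_maxima(-x)
    excursion <- if (length(mins) > 0)
      median(x[cand]) - median(x[mins]) else max(x) - min(x)
    min_prominence <- max(prominence_floor, 0.2 * excursion)
  }
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (length(keep) == 0L)
    abort_respdepth("signal", "no respiration detected (no prominent peaks)")
  # enforce minimum spacing, keeping the taller peak
  min_gap <- min_interval_s * sig$sample_rate
  ord <- order(x[keep], promk, decreasing = TRUE)
  sel <- logical(length(keep))
  for (i in ord) {
    if (!any(sel & abs(keep - keep[i]) < min_gap)) sel[i] <- TRUE
  }
  peaks <- sort(keep[sel])

  valleys <- integer(0)
  if (peaks[1] > 2L) {
    seg <- 1:(peaks[1] - 1L)
    v <- seg[which.min(x[seg])]
    # a leading minimum is a genuine valley only when it is interior:
    # a boundary minimum means the recording started mid-breath and the
    # first partial breath is dropped
    if (v > 1L && v < peaks[1]) valleys <- v
  }
  if (length(peaks) > 1L) {
    for (i in seq_len(length(peaks) - 1L)) {
      seg <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
      valleys <- c(valleys, seg[which.min(x[seg])])
    }
  }
  # keep only complete valley -> peak pairs
  if (length(valleys) == 0L || valleys[1] > peaks[1]) {
    peaks <- peaks[-1L]
    if (length(peaks) == 0L)
      abort_respdepth("signal", "no complete breath (no preceding valley)")
  }
  prev_valley <- vapply(peaks, function(p) max(valleys[valleys < p]),
                        integer(1))
  amplitudes <- x[peaks] - x[prev_valley]
  bad <- amplitudes <= 0
  if (any(bad)) {
    peaks <- peaks[!bad]
    prev_valley <- prev_valley[!bad]
    amplitudes <- amplitudes[!bad]
  }
  if (length(peaks) == 0L)
    abort_respdepth("signal", "no respiration detected")
  ev <- structure(list(
    peaks = peaks,
    valleys = valleys,
    peak_times_s = sig$t[peaks],
    valley_times_s = sig$t[valleys],
    amplitudes = amplitudes,
    intervals = if (length(peaks) > 1L) diff(sig$t[peaks]) else numeric(0),
    sample_rate = sig$sample_rate
  ), class = "breath_events")
  check_alternation(ev)
  ev
}

# peaks and valleys must strictly alternate in time; asserted on every
# detector output
check_alternation <- function(ev) {
  idx <- sort(c(ev$peaks, ev$valleys))
  kind <- ifelse(idx %in% ev$peaks, "p", "v")
  if (any(kind[-1] == kind[-length(kind)]))
    abort_respdepth("signal", "peaks and valleys do not alternate")
  invisible(ev)
}

#' @export
print.breath_events <- function(x, ...) {
  cat(sprintf(paste0("breath_events: %d breaths, mean amplitude %.2f, ",
                     "mean interval %.2f s\n"),
              length(x$peaks), mean(x$amplitudes),
              if (length(x$intervals)) mean(x$intervals) else NA))
  invisible(x)
}

# (start, end) sample windows, one full breath each, from consecutive
# valleys; a trailing window closes at the signal end when the last peak
# has no following valley.
breath_windows <- function(events, n_samples) {
  v <- events$valleys
  if (length(v) >= 2L) {
    out <- lapply(seq_len(length(v) - 1L), function(i) c(v[i], v[i + 1L]))
  } else {
    out <- list()
  }
  last_peak <- events$peaks[length(events$peaks)]
  if (length(v) > 0 && v[length(v)] < last_peak)
    out <- c(out, list(c(v[length(v)], n_samples)))
  out
}
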