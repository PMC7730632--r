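#' Tentative region of interest from shoulder geometry
#'
#' The rectangle top sits at the lower of the two shoulders, the sides
#' are trimmed inward from each shoulder by an approximate arm width,
#' and the bottom is provisionally the lower edge of the image; the true
#' bottom is fixed later by [finalize_roi()].
#'
#' @param shoulders shoulder pair from [detect_shoulders()].
#' @param frame_height,frame_width frame dimensions in pixels.
#' @param arm_width_px margin trimmed inside each shoulder, pixels; must
#'   be less than half the shoulder distance.
#' @return ROI rectangle: list `top, bottom, left, right` (0-based,
#'   half-open) with `stage = "tentative"`.
#' @export
build_tentative_roi <- function(shoulders, frame_height, frame_width,
                                arm_width_px) {
  l <- shoulders$left; r <- shoulders$right
  if (l[2] >= r[2])
    abort_respdepth("validation", "left shoulder must be left of right")
  stopifnot_scalar_number(arm_width_px, "arm_width_px", min = 0)
  top <- max(l[1], r[1])
  left <- l[2] + arm_width_px
  right <- r[2] - arm_width_px
  if (left >= right)
    abort_respdepth("geometry",
                    "arm width margin leaves an empty ROI (left >= right)")
  roi <- list(top = as.integer(top), bottom = as.integer(frame_height),
              left = as.integer(round(left)), right = as.integer(round(right)),
              stage = "tentative")
  validate_roi(roi, frame_height, frame_width)
}

validate_roi <- function(roi, frame_height = Inf, frame_width = Inf) {
  if (!(roi$top < roi$bottom && roi$left < roi$right))
    abort_respdepth("geometry", "degenerate ROI rectangle")
  if (roi$top < 0 || roi$left < 0 ||
      roi$bottom > frame_height || roi$right > frame_width)
    abort_respdepth("geometry", "ROI exceeds frame bounds")
  roi
}

#' Unit-area grid over an ROI
#'
#' Tiles the rectangle with square unit areas of `unit_size` pixels
#' anchored every `stride` pixels; every unit lies fully inside the ROI.
#' Mean depth over a unit suppresses the per-pixel random error of the
#' sensor, which is strongly correlated only between close pixels.
#'
#' @param roi rectangle from [build_tentative_roi()].
#' @param unit_size unit side, pixels (default 19).
#' @param stride anchor spacing, pixels (default 10).
#' @return A unit grid: list with `unit_size`, `stride`, `n_rows`,
#'   `n_cols`, `row_tops`, `col_lefts` (0-based anchor coordinates) and
#'   the originating `roi`.
#' @export
build_unit_grid <- function(roi, unit_size = 19L, stride = 10L) {
  unit_size <- as.integer(unit_size); stride <- as.integer(stride)
  if (unit_size < stride)
    abort_respdepth("validation", "`unit_size` must be >= `stride`")
  h <- roi$bottom - roi$top
  w <- roi$right - roi$left
  if (h < unit_size || w < unit_size)
    abort_respdepth("geometry", "ROI is smaller than one unit area")
  n_rows <- (h - unit_size) %/% stride + 1L
  n_cols <- (w - unit_size) %/% stride + 1L
  list(unit_size = unit_size, stride = stride,
       n_rows = n_rows, n_cols = n_cols,
       row_tops = roi$top + stride * (seq_len(n_rows) - 1L),
       col_lefts = roi$left + stride * (seq_len(n_cols) - 1L),
       roi = roi)
}

# Summed-area tables for one frame: values and valid-pixel counts.
# Returned with a leading zero row/col so that block sums are
# S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1] for 1-based [r1..r2].
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

block_sums <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

#' Per-unit depth waveforms
#'
#' For every unit area and every frame, the mean depth of the unit's
#' valid (non-zero) pixels is computed, then each unit's series is
#' linearly interpolated onto a uniform clock at `sample_rate` spanning
#' the sequence.  Units whose share of invalid pixels exceeds 50 % in
#' more than 10 % of frames are flagged invalid rather than silently
#' zeroed.
#'
#' @param seq a [depth_sequence()].
#' @param grid unit grid from [build_unit_grid()].
#' @param sample_rate resampling rate, Hz (default 30).
#' @return List with `values` (array `n_rows x n_cols x n_samples`, mm),
#'   `validity` (logical `n_rows x n_cols`), `t` (sample times, s),
#'   `sample_rate`, and the `grid`.
#' @export
extract_unit_waveforms <- function(seq, grid, sample_rate = 30) {
  stopifnot_scalar_number(sample_rate, "sample_rate", min = 1)
  us <- grid$unit_size
  r1 <- grid$row_tops + 1L; r2 <- grid$row_tops + us
  c1 <- grid$col_lefts + 1L; c2 <- grid$col_lefts + us
  if (max(r2) > seq$height || max(c2) > seq$width)
    abort_respdepth("geometry", "unit grid exceeds frame bounds")
  nr <- grid$n_rows; nc <- grid$n_cols; nf <- seq$n_frames
  R1 <- rep(r1, times = nc); R2 <- rep(r2, times = nc)
  C1 <- rep(c1, each = nr); C2 <- rep(c2, each = nr)

  # work on the grid's bounding block only; anchors re-based into it
  rr <- min(r1):max(r2); cc <- min(c1):max(c2)
  R1 <- R1 - min(r1) + 1L; R2 <- R2 - min(r1) + 1L
  C1 <- C1 - min(c1) + 1L; C2 <- C2 - min(c1) + 1L
  raw <- matrix(NA_real_, nr * nc, nf)     # unit means per native frame
  frac_invalid <- matrix(0, nr * nc, nf)
  for (f in seq_len(nf)) {
    fr <- seq$frames[rr, cc, f]
    valid <- fr > 0L
    Sv <- integral_image(fr * valid)
    Sc <- integral_image(valid * 1L)
    cnt <- block_sums(Sc, R1, R2, C1, C2)
    tot <- block_sums(Sv, R1, R2, C1, C2)
    raw[, f] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    frac_invalid[, f] <- 1 - cnt / (us * us)
  }
  validity <- rowMeans(frac_invalid > 0.5) <= 0.10 & rowSums(!is.na(raw)) >= 2
  if (!any(validity))
    abort_respdepth("signal", "all unit areas are invalid")

  tgrid <- uniform_time_grid(seq$timestamps, sample_rate)
  values <- array(NA_real_, c(nr, nc, length(tgrid)))
  for (u in which(validity)) {
    ok <- !is.na(raw[u, ])
    values[((u - 1L) %% nr) + 1L, ((u - 1L) %/% nr) + 1L, ] <-
      approx(seq$timestamps[ok], raw[u, ok], xout = tgrid, rule = 2)$y
  }
  list(values = values,
       validity = matrix(validity, nr, nc),
       t = tgrid, sample_rate = sample_rate, grid = grid)
}

uniform_time_grid <- function(timestamps, rate) {
  t0 <- timestamps[1]
  n <- floor((timestamps[length(timestamps)] - t0) * rate) + 1
  t0 + (seq_len(n) - 1) / rate
}

#' Row waveforms and amplitude ratios
#'
#' Averages the unit waveforms of each grid row into a row waveform,
#' measures each row's mean per-breath depth excursion (max minus min
#' within each breath window), and normalises the excursions into an
#' amplitude ratio summing to one, with its cumulative sum from the top
#' row.  Rows without any valid unit are dropped before normalisation
#' and reported in the result.
#'
#' Row waveforms are smoothed with the same zero-phase moving average as
#' the main signal before the excursions are measured; without it,
#' units straddling a depth edge turn single-frame sensor dropouts into
#' multi-millimetre spikes ("flying pixels") that inflate the amplitude
#' of rows carrying no breathing motion.
#'
#' @param units unit waveforms from [extract_unit_waveforms()].
#' @param breath_windows list (or 2-column matrix) of `(start, end)`
#'   sample indices (1-based) delimiting individual breaths, obtained
#'   from one global breath segmentation of the tentative-ROI mean
#'   signal.
#' @param smooth_window_s smoothing window applied to each row waveform
#'   before amplitude measurement, seconds (default 0.5, matching
#'   [resp_smooth()]).
#' @return List with `row_signals` (matrix `n_kept x n_samples`,
#'   smoothed), `row_index` (grid row of each kept row), `row_amplitude`
#'   (mm), `amplitude_ratio`, `cumulative_ratio`, `dropped_rows`.
#' @export
compute_row_waveforms <- function(units, breath_windows,
                                  smooth_window_s = 0.5) {
  if (is.matrix(breath_windows))
    breath_windows <- split(breath_windows, row(breath_windows)[, 1])
  if (length(breath_windows) == 0L)
    abort_respdepth("signal", "no breath windows supplied")
  nr <- dim(units$values)[1]
  ns <- dim(units$values)[3]
  keep <- which(rowSums(units$validity) > 0)
  if (length(keep) == 0L)
    abort_respdepth("signal", "no grid row has a valid unit")
  row_signals <- matrix(NA_real_, length(keep), ns)
  for (k in seq_along(keep)) {
    i <- keep[k]
    vcols <- which(units$validity[i, ])
    sl <- units$values[i, vcols, , drop = FALSE]
    row_signals[k, ] <- apply(sl, 3, mean)
  }
  wsm <- round(smooth_window_s * units$sample_rate)
  if (wsm >= 1)
    row_signals <- t(apply(row_signals, 1, moving_average, w = wsm))
  amp <- vapply(seq_along(keep), function(k) {
    per_breath <- vapply(breath_windows, function(wd) {
      a <- max(1L, as.integer(wd[1])); b <- min(ns, as.integer(wd[2]))
      if (b <= a) return(NA_real_)
      seg <- row_signals[k, a:b]
      max(seg) - min(seg)
    }, numeric(1))
    mean(per_breath, na.rm = TRUE)
  }, numeric(1))
  total <- sum(amp)
  ratio <- if (total > 0) amp / total else rep(1 / length(amp), length(amp))
  list(row_signals = row_signals,
       row_index = keep,
       row_amplitude = amp,
       amplitude_ratio = ratio,
       cumulative_ratio = cumsum(ratio),
       dropped_rows = setdiff(seq_len(nr), keep))
}

#' Fix the ROI bottom by cumulative amplitude ratio
#'
#' Rows contribute to the breathing excursion unevenly; integrating the
#' per-row amplitude ratio from the ROI top and cutting at the first row
#' where the running sum reaches the cutoff (default 90 %) excludes the
#' bottom rows whose motion contributes only the residual tail.  The
#' final bottom is the lower edge of that row's unit areas; top, left
#' and right are unchanged.
#'
#' @param tentative tentative ROI from [build_tentative_roi()].
#' @param rows row waveform set from [compute_row_waveforms()].
#' @param grid unit grid from [build_unit_grid()].
#' @param cutoff cumulative ratio to attain, in (0, 1]; default 0.90.
#' @return Final ROI rectangle (`stage = "final"`) with attribute
#'   `cut_row` (the 1-based kept-row index at the crossing).
#' @export
finalize_roi <- function(tentative, rows, grid, cutoff = 0.90) {
  stopifnot_scalar_number(cutoff, "cutoff", min = 0, max = 1,
                          strict_min = TRUE)
  cum <- rows$cumulative_ratio
  istar <- which(cum >= cutoff - 1e-12)[1]
  if (is.na(istar)) istar <- length(cum)  # cumulative always ends at 1
  grid_row <- rows$row_index[istar]
  bottom <- grid$row_tops[grid_row] + grid$unit_size
  roi <- list(top = tentative$top, bottom = as.integer(bottom),
              left = tentative$left, right = tentative$right,
              stage = "final")
  validate_roi(roi)
  attr(roi, "cut_row") <- istar
  roi
}
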