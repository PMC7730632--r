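#' Depth-frame sequence
#'
#' Container for a timestamped stack of depth frames in integer
#' millimetres, the raw record of a time-of-flight camera.  Depth value
#' 0 is reserved for "no reading" (the ToF dropout convention).
#'
#' @param frames integer 3-D array `[height x width x n_frames]`, depth
#'   in mm, 0 = invalid pixel, values at most 65535 (16-bit range).
#' @param timestamps numeric vector of per-frame times in seconds since
#'   sequence start, strictly increasing, one per frame.
#' @return An object of class `depth_sequence` with fields `frames`,
#'   `timestamps`, `height`, `width`, `n_frames`.
#' @export
depth_sequence <- function(frames, timestamps) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort_respdepth("validation",
                    "`frames` must be a 3-D array [height x width x n]")
  d <- dim(frames)
  if (d[3] < 2L)
    abort_respdepth("validation", "a depth sequence needs at least 2 frames")
  if (length(timestamps) != d[3])
    abort_respdepth("validation", "one timestamp per frame is required")
  if (any(!is.finite(timestamps)) || any(diff(timestamps) <= 0))
    abort_respdepth("validation", "timestamps must be strictly increasing")
  if (min(frames) < 0 || max(frames) > 65535)
    abort_respdepth("validation", "depth values must be in [0, 65535] mm")
  storage.mode(frames) <- "integer"
  structure(list(frames = frames,
                 timestamps = as.numeric(timestamps),
                 height = d[1], width = d[2], n_frames = d[3]),
            class = "depth_sequence")
}

#' @export
print.depth_sequence <- function(x, ...) {
  cat(sprintf("depth_sequence: %d frames of %d x %d px, %.2f s @ ~%.1f fps\n",
              x$n_frames, x$height, x$width,
              diff(range(x$timestamps)),
              (x$n_frames - 1) / diff(range(x$timestamps))))
  invisible(x)
}

#' Write a depth sequence to a frame directory
#'
#' The canonical on-disk interchange is a directory of 16-bit grayscale
#' TIFF frames named `frame_000001.tif`, ... plus a `timestamps.csv`
#' with columns `frame,time_s`.  The encoding is lossless: a read after
#' a write returns bit-identical depth values and timestamps.
#'
#' @param seq a [depth_sequence()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_depth_sequence <- function(seq, path) {
  if (!inherits(seq, "depth_sequence"))
    abort_respdepth("validation", "`seq` must be a depth_sequence")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    abort_respdepth("io", sprintf("cannot create directory %s", path))
  for (i in seq_len(seq$n_frames)) {
    f <- file.path(path, sprintf("frame_%06d.tif", i))
    ok <- tryCatch(
      tiff::writeTIFF(seq$frames[, , i] / 65535, f, bits.per.sample = 16L),
      error = function(e) NA)
    if (is.na(ok[1]))
      abort_respdepth("io", sprintf("cannot write frame file %s", f))
  }
  write.csv(data.frame(frame = seq_len(seq$n_frames),
                       time_s = seq$timestamps),
            file.path(path, "timestamps.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a depth sequence from a frame directory
#'
#' Reads the container written by [write_depth_sequence()].  Frames are
#' ordered by the timestamps file; mixed frame dimensions or
#' non-monotonic timestamps are rejected.
#'
#' @param path directory containing `frame_*.tif` and `timestamps.csv`.
#' @return A [depth_sequence()].
#' @export
read_depth_sequence <- function(path) {
  ts_file <- file.path(path, "timestamps.csv")
  if (!dir.exists(path))
    abort_respdepth("format", sprintf("no such directory: %s", path))
  if (!file.exists(ts_file))
    abort_respdepth("format", sprintf("missing timestamps file: %s", ts_file))
  ts <- read.csv(ts_file)
  if (!all(c("frame", "time_s") %in% names(ts)))
    abort_respdepth("format", "timestamps.csv must have columns frame,time_s")
  ord <- order(ts$time_s)
  ts <- ts[ord, , drop = FALSE]
  if (any(diff(ts$time_s) <= 0))
    abort_respdepth("validation", "timestamps must be strictly increasing")
  files <- file.path(path, sprintf("frame_%06d.tif", ts$frame))
  missing <- !file.exists(files)
  if (any(missing))
    abort_respdepth("format",
                    sprintf("missing frame file(s): %s",
                            paste(basename(files[missing]), collapse = ", ")))
  frames <- NULL
  for (i in seq_along(files)) {
    m <- round(tiff::readTIFF(files[i]) * 65535)
    if (is.null(frames)) {
      frames <- array(0L, dim = c(nrow(m), ncol(m), length(files)))
    } else if (nrow(m) != dim(frames)[1] || ncol(m) != dim(frames)[2]) {
      abort_respdepth("validation",
                      sprintf("frame %d has different dimensions", ts$frame[i]))
    }
    frames[, , i] <- as.integer(m)
  }
  depth_sequence(frames, ts$time_s)
}

#' Reference volume trace
#'
#' A spirometer-style record: instantaneous lung volume over time plus a
#' binary trigger channel marking the depth-camera measurement epoch.
#'
#' @param time_s sample times, seconds, strictly increasing.
#' @param volume_L instantaneous volume, litres.
#' @param trigger 0/1 flag per sample; at least one sample must be 1.
#' @return A `data.frame` of class `reference_trace`.
#' @export
reference_trace <- function(time_s, volume_L, trigger) {
  n <- length(time_s)
  if (length(volume_L) != n || length(trigger) != n)
    abort_respdepth("validation", "trace columns must have equal length")
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0))
    abort_respdepth("validation", "time_s must be strictly increasing")
  if (!all(trigger %in% c(0, 1)))
    abort_respdepth("validation", "trigger must be 0/1")
  if (!any(trigger == 1))
    abort_respdepth("validation", "trace contains no trigger = 1 sample")
  structure(data.frame(time_s = as.numeric(time_s),
                       volume_L = as.numeric(volume_L),
                       trigger = as.integer(trigger)),
            class = c("reference_trace", "data.frame"))
}

#' Read a reference volume trace from CSV
#'
#' @param path CSV with header columns `time_s`, `volume_L`, `trigger`
#'   (comma separated, `.` decimal).
#' @return A [reference_trace()].
#' @export
read_reference_trace <- function(path) {
  if (!file.exists(path))
    abort_respdepth("format", sprintf("no such file: %s", path))
  df <- read.csv(path)
  need <- c("time_s", "volume_L", "trigger")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort_respdepth("format",
                    paste0("reference trace is missing column(s): ",
                           paste(miss, collapse = ", ")))
  reference_trace(df$time_s, df$volume_L, df$trigger)
}

#' Write a reference volume trace to CSV
#'
#' @param ref a [reference_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_trace <- function(ref, path) {
  if (!inherits(ref, "reference_trace"))
    abort_respdepth("validation", "`ref` must be a reference_trace")
  write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' Trigger-based time alignment
#'
#' The acquisition PC raises a trigger line in the reference recording
#' at the instant the depth camera starts.  The returned offset is the
#' reference-clock time of the trigger onset (first 0 to 1 transition;
#' sample 0 if the trace begins high), so that depth timestamp `t`
#' corresponds to reference time `t + offset`, i.e. downstream
#' comparisons use `ref$time_s - offset` on the depth clock.
#'
#' @param seq a [depth_sequence()] (only checked for validity).
#' @param ref a [reference_trace()].
#' @return Offset in seconds.
#' @export
align_by_trigger <- function(seq, ref) {
  if (!inherits(ref, "reference_trace"))
    abort_respdepth("validation", "`ref` must be a reference_trace")
  tr <- ref$trigger
  onset <- if (tr[1] == 1) 1L else which(diff(tr) == 1)[1] + 1L
  if (is.na(onset))
    abort_respdepth("validation", "trace contains no trigger onset")
  ref$time_s[onset]
}
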