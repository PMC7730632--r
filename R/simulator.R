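# Synthetic breathing-torso simulator.
#
# Renders ground-truthed depth sequences of a seated subject facing a
# ToF camera: a silhouette (head, neck, trapezoidal torso) at a fixed
# camera distance, compartmental chest/abdomen motion, postural sway,
# clothing smoothing of the displacement field, sensor noise and
# dropout.  Orthographic projection with a fixed mm-per-pixel pitch is
# used throughout: the pipeline consumes depth values, not geometry, so
# perspective rendering would add nothing testable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic torso scene
#'
#' Builds the static geometry of the simulated scene: silhouette,
#' disjoint chest and abdomen region masks, ground-truth shoulder
#' pixels, and the mm-per-pixel pitch implied by the camera distance
#' and a 70.6 degree horizontal field of view.  A deterministic surface
#' relief (gentle corrugation plus transverse body curvature) is added
#' so that integer-mm quantisation of the rendered depth dithers away
#' under unit-area averaging, as it does on a real curved body.
#'
#' @param frame_height,frame_width frame size, pixels (default 424 x 512).
#' @param camera_distance_mm distance of the chest wall (default 1000).
#' @param background_mm backdrop depth (default 3000).
#' @param chest_circumference_cm girth used to scale the torso width
#'   (default 95).
#' @param center_col_frac horizontal body position as a fraction of the
#'   frame width (default 0.5).
#' @return Object of class `torso_scene`: masks, truth, `pitch_mm_per_px`,
#'   region areas in m2.
#' @export
torso_scene <- function(frame_height = 424L, frame_width = 512L,
                        camera_distance_mm = 1000,
                        background_mm = 3000,
                        chest_circumference_cm = 95,
                        center_col_frac = 0.5) {
  h <- as.integer(frame_height); w <- as.integer(frame_width)
  stopifnot_scalar_number(camera_distance_mm, "camera_distance_mm", min = 1)
  stopifnot_scalar_number(background_mm, "background_mm",
                          min = camera_distance_mm, strict_min = TRUE)
  pitch <- 2 * camera_distance_mm * tan(70.6 / 2 * pi / 180) / w

  cc <- center_col_frac * (w - 1)          # 0-based centre column
  torso_w_px <- (10 * chest_circumference_cm / pi) / pitch
  shoulder_row <- round(0.25 * h)
  bottom_row <- round(0.94 * h)
  head_top <- round(0.06 * h)
  neck_top <- round(0.18 * h)
  head_c_row <- (head_top + neck_top) / 2
  head_r_row <- (neck_top - head_top) / 2
  head_r_col <- 0.8 * head_r_row
  neck_hw <- 0.25 * torso_w_px / 2
  hip_hw <- 0.46 * torso_w_px
  top_hw <- torso_w_px / 2

  rows <- matrix(seq_len(h) - 1, h, w)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)

  torso_hw <- top_hw + (hip_hw - top_hw) *
    pmax(0, pmin(1, (rows - shoulder_row) / (bottom_row - shoulder_row)))
  torso <- rows >= shoulder_row & rows <= bottom_row &
    abs(cols - cc) <= torso_hw
  neck <- rows >= neck_top & rows < shoulder_row & abs(cols - cc) <= neck_hw
  head <- ((rows - head_c_row) / head_r_row)^2 +
    ((cols - cc) / head_r_col)^2 <= 1
  sil <- torso | neck | head
  if (!any(sil))
    abort_respdepth("validation", "scene geometry produced an empty silhouette")

  # regions: central 80 % of the local torso width; chest over the upper
  # 4-42 % of the torso span, abdomen over 42-85 %; the remaining lower
  # 15 % is static (hips/lap), the area the final ROI should drop
  span <- bottom_row - shoulder_row
  reg_hw <- 0.8 * torso_hw
  chest <- torso & abs(cols - cc) <= reg_hw &
    rows >= shoulder_row + 0.04 * span & rows < shoulder_row + 0.42 * span
  abdomen <- torso & abs(cols - cc) <= reg_hw &
    rows >= shoulder_row + 0.42 * span & rows < shoulder_row + 0.85 * span
  if (any(chest & abdomen))
    abort_respdepth("validation", "chest and abdomen regions overlap")

  # static surface relief: transverse curvature + gentle corrugation
  u <- pmin(1, abs(cols - cc) / pmax(torso_hw, 1))
  curvature <- 60 * (1 - sqrt(pmax(0, 1 - u^2)))
  relief <- 2 * sin(2 * pi * rows / 13.7) + 2 * sin(2 * pi * cols / 9.3)
  base <- matrix(background_mm, h, w)
  base[sil] <- camera_distance_mm + curvature[sil] + relief[sil]

  srow <- shoulder_row
  scols <- range(which(torso[srow + 1L, ])) - 1L
  structure(list(
    frame_height = h, frame_width = w,
    camera_distance_mm = camera_distance_mm,
    background_mm = background_mm,
    pitch_mm_per_px = pitch,
    silhouette = sil, chest_mask = chest, abdomen_mask = abdomen,
    base_depth = base,
    shoulders_true = list(left = c(srow, scols[1]),
                          right = c(srow, scols[2])),
    chest_area_m2 = sum(chest) * (pitch / 1000)^2,
    abdomen_area_m2 = sum(abdomen) * (pitch / 1000)^2,
    shoulder_row = srow, torso_bottom_row = bottom_row
  ), class = "torso_scene")
}

#' @export
print.torso_scene <- function(x, ...) {
  cat(sprintf(paste0("torso_scene: %d x %d px @ %.2f mm/px, chest %.3f m2, ",
                     "abdomen %.3f m2\n"),
              x$frame_height, x$frame_width, x$pitch_mm_per_px,
              x$chest_area_m2, x$abdomen_area_m2))
  invisible(x)
}

#' Breathing program
#'
#' Sinusoidal compartmental breathing: chest and abdomen move between 0
#' (end-expiration) and their amplitude (end-inspiration), the abdomen
#' optionally lagging the chest (thoracoabdominal asynchrony).  The
#' `"deep"` pattern defaults emulate a short run of self-paced deep
#' breaths: 2.5 x the quiet amplitudes at 0.6 x the quiet rate, five
#' breaths.
#'
#' @param pattern `"normal"` or `"deep"`; sets the defaults below.
#' @param rr_bpm breathing rate, breaths/min, in (4, 40).
#' @param chest_amp_mm,abdomen_amp_mm compartment amplitudes, mm.
#' @param phase_lag_deg abdomen phase lag behind the chest, degrees
#'   in [0, 180].
#' @param duration_s recording length, seconds; for `"deep"` derived
#'   from `n_breaths` when missing.
#' @param n_breaths alternative to `duration_s`.
#' @return Object of class `breathing_program`.
#' @export
breathing_program <- function(pattern = c("normal", "deep"),
                              rr_bpm = NULL,
                              chest_amp_mm = NULL, abdomen_amp_mm = NULL,
                              phase_lag_deg = 0,
                              duration_s = NULL, n_breaths = NULL) {
  pattern <- match.arg(pattern)
  if (pattern == "normal") {
    if (is.null(rr_bpm)) rr_bpm <- 14
    if (is.null(chest_amp_mm)) chest_amp_mm <- 5
    if (is.null(abdomen_amp_mm)) abdomen_amp_mm <- 4
    if (is.null(duration_s) && is.null(n_breaths)) duration_s <- 60
  } else {
    if (is.null(rr_bpm)) rr_bpm <- 14 * 0.6
    if (is.null(chest_amp_mm)) chest_amp_mm <- 5 * 2.5
    if (is.null(abdomen_amp_mm)) abdomen_amp_mm <- 4 * 2.5
    if (is.null(duration_s) && is.null(n_breaths)) n_breaths <- 5
  }
  if (is.null(duration_s)) duration_s <- n_breaths * 60 / rr_bpm
  if (rr_bpm <= 4 || rr_bpm >= 40)
    abort_respdepth("validation", "rr_bpm must be in (4, 40)")
  if (chest_amp_mm < 0 || abdomen_amp_mm < 0)
    abort_respdepth("validation", "amplitudes must be >= 0")
  if (phase_lag_deg < 0 || phase_lag_deg > 180)
    abort_respdepth("validation", "phase_lag_deg must be in [0, 180]")
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  structure(list(pattern = pattern, rr_bpm = rr_bpm,
                 chest_amp_mm = chest_amp_mm,
                 abdomen_amp_mm = abdomen_amp_mm,
                 phase_lag_deg = phase_lag_deg,
                 duration_s = duration_s),
            class = "breathing_program")
}

#' Sensor and motion noise model
#'
#' Per-pixel Gaussian depth noise, random dropout (pixels set to 0,
#' the sensor's no-reading value), slow whole-body depth sway, optional
#' vertical (row) sway, and clothing smoothing of the displacement
#' field.  Defaults are plausible ToF figures: 1.5 mm pixel noise and
#' 0.5 % dropout; sway and blur default to off.  Sway with
#' `sway_phase_deg = 90` and `sway_period_s` equal to the breath period
#' is in anti-phase with the breathing displacement, the mechanism that
#' makes whole-body backward motion cancel chest motion.
#'
#' @param pixel_sd_mm Gaussian depth noise SD, mm.
#' @param dropout_prob per-pixel probability of a dropped reading.
#' @param sway_amp_mm whole-body depth sway amplitude, mm.
#' @param sway_period_s sway period, seconds (default 60: slow postural
#'   drift).
#' @param sway_phase_deg sway phase at t = 0, degrees.
#' @param vertical_sway_px amplitude of vertical image sway, pixels.
#' @param clothing_blur_px Gaussian sigma smoothing the displacement
#'   field (0 = undressed skin).
#' @param seed RNG seed making the rendering reproducible.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(pixel_sd_mm = 1.5, dropout_prob = 0.005,
                        sway_amp_mm = 0, sway_period_s = 60,
                        sway_phase_deg = 0,
                        vertical_sway_px = 0, clothing_blur_px = 0,
                        seed = 1L) {
  for (nm in c("pixel_sd_mm", "dropout_prob", "sway_amp_mm",
               "sway_period_s", "sway_phase_deg",
               "vertical_sway_px", "clothing_blur_px"))
    stopifnot_scalar_number(get(nm), nm, min = 0)
  if (dropout_prob > 1)
    abort_respdepth("validation", "dropout_prob must be <= 1")
  structure(list(pixel_sd_mm = pixel_sd_mm, dropout_prob = dropout_prob,
                 sway_amp_mm = sway_amp_mm, sway_period_s = sway_period_s,
                 sway_phase_deg = sway_phase_deg,
                 vertical_sway_px = vertical_sway_px,
                 clothing_blur_px = clothing_blur_px,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free model (all noise sources off)
#' @param seed RNG seed (unused when everything is off, kept for
#'   interface symmetry).
#' @return A [noise_model()] with every source zero.
#' @export
noise_none <- function(seed = 1L) {
  noise_model(pixel_sd_mm = 0, dropout_prob = 0, sway_amp_mm = 0,
              clothing_blur_px = 0, seed = seed)
}

#' Render a ground-truthed depth sequence
#'
#' Per frame, the base depth map (background plus the static torso
#' surface) is displaced toward the camera by the compartmental
#' breathing field, optionally smoothed by clothing, shifted by whole
#' body sway, then degraded by sensor noise and dropout and quantised
#' to integer millimetres.  Ground truth carries the instantaneous
#' displaced volume (surface integral of the displacement field over
#' the torso), the analytic per-breath tidal volume and peak times, the
#' programmed rate, and the true shoulder pixels.
#'
#' @param scene a [torso_scene()].
#' @param program a [breathing_program()].
#' @param noise a [noise_model()].
#' @param fps native frame rate of the rendering.
#' @return List with `seq` (a [depth_sequence()]) and `truth` (class
#'   `torso_truth`).
#' @export
render_sequence <- function(scene, program, noise = noise_none(), fps = 30) {
  stopifnot_scalar_number(fps, "fps", min = 1)
  h <- scene$frame_height; w <- scene$frame_width
  n <- max(2L, floor(program$duration_s * fps) + 1L)
  t <- (seq_len(n) - 1) / fps
  f <- program$rr_bpm / 60
  lag <- program$phase_lag_deg * pi / 180

  Mc <- scene$chest_mask * 1
  Ma <- scene$abdomen_mask * 1
  if (noise$clothing_blur_px > 0) {
    Mc <- EBImage::imageData(EBImage::gblur(Mc, sigma = noise$clothing_blur_px))
    Ma <- EBImage::imageData(EBImage::gblur(Ma, sigma = noise$clothing_blur_px))
    Mc[!scene$silhouette] <- 0
    Ma[!scene$silhouette] <- 0
  }
  sil <- scene$silhouette
  base <- scene$base_depth

  px_area_L_per_mm <- scene$pitch_mm_per_px^2 / 1e6
  alpha <- sum(Mc) * program$chest_amp_mm * px_area_L_per_mm
  beta <- sum(Ma) * program$abdomen_amp_mm * px_area_L_per_mm

  s_chest <- (1 - cos(2 * pi * f * t)) / 2
  s_abd <- (1 - cos(2 * pi * f * t - lag)) / 2
  c_t <- program$chest_amp_mm * s_chest
  a_t <- program$abdomen_amp_mm * s_abd
  sway_t <- noise$sway_amp_mm *
    sin(2 * pi * t / noise$sway_period_s + noise$sway_phase_deg * pi / 180)
  vshift_t <- round(noise$vertical_sway_px *
                      sin(2 * pi * t / noise$sway_period_s +
                            noise$sway_phase_deg * pi / 180))

  frames <- array(0L, dim = c(h, w, n))
  npx <- h * w
  idx <- which(sil)
  base_sil <- base[idx]
  Mc_sil <- Mc[idx]
  Ma_sil <- Ma[idx]
  base_int <- matrix(as.integer(round(base)), h, w)
  clean_path <- noise$pixel_sd_mm == 0 && noise$dropout_prob == 0
  with_seed(noise$seed, {
    for (k in seq_len(n)) {
      vals <- base_sil - c_t[k] * Mc_sil - a_t[k] * Ma_sil - sway_t[k]
      if (clean_path && vshift_t[k] == 0) {
        D <- base_int
        D[idx] <- as.integer(pmin(pmax(round(vals), 1), 65535))
      } else {
        D <- base
        D[idx] <- vals
        if (vshift_t[k] != 0) {
          s <- vshift_t[k]
          D2 <- matrix(scene$background_mm, h, w)
          if (s > 0) D2[(1 + s):h, ] <- D[1:(h - s), ]
          else D2[1:(h + s), ] <- D[(1 - s):h, ]
          D <- D2
        }
        if (noise$pixel_sd_mm > 0)
          D <- D + rnorm(npx, sd = noise$pixel_sd_mm)
        D <- round(D)
        D[D < 1] <- 1
        D[D > 65535] <- 65535
        if (noise$dropout_prob > 0)
          D[runif(npx) < noise$dropout_prob] <- 0
        storage.mode(D) <- "integer"
      }
      frames[, , k] <- D
    }
  })

  # analytic instantaneous volume and per-breath truth
  V <- alpha * s_chest + beta * s_abd
  R <- sqrt(alpha^2 + beta^2 + 2 * alpha * beta * cos(lag)) / 1  # L
  psi <- atan2(beta * sin(lag), alpha + beta * cos(lag))
  kmax <- floor((2 * pi * f * t[n] - psi - pi) / (2 * pi))
  peak_times <- if (kmax >= 0)
    (psi + pi + 2 * pi * (0:kmax)) / (2 * pi * f) else numeric(0)

  truth <- structure(list(
    rr_bpm = program$rr_bpm,
    tv_L = rep(R, max(length(peak_times), 1L)),
    peak_times_s = peak_times,
    volume_t_s = t, volume_L = V,
    shoulders = scene$shoulders_true,
    chest_area_m2 = scene$chest_area_m2,
    abdomen_area_m2 = scene$abdomen_area_m2,
    duration_s = program$duration_s,
    fps = fps
  ), class = "torso_truth")

  list(seq = depth_sequence(frames, t), truth = truth)
}

#' Render a multi-phase breathing session
#'
#' Concatenates several breathing programs into one continuous recording
#' (e.g. a minute of quiet breathing followed by five deep breaths, the
#' usual calibration protocol).  Each phase starts at end-expiration, so
#' the displacement field is continuous across phase boundaries.  Ground
#' truths are merged with peak times and the volume trace shifted onto
#' the session clock.
#'
#' @param scene a [torso_scene()].
#' @param programs list of [breathing_program()]s, rendered in order.
#' @param noise a [noise_model()]; phase k uses `seed + k - 1`.
#' @param fps native frame rate.
#' @return List with `seq` and merged `truth`, as [render_sequence()].
#' @export
render_session <- function(scene, programs, noise = noise_none(), fps = 30) {
  if (length(programs) == 0L)
    abort_respdepth("validation", "at least one breathing program is needed")
  frames <- NULL; ts <- numeric(0)
  tv <- numeric(0); pk <- numeric(0); vt <- numeric(0); vv <- numeric(0)
  t0 <- 0
  for (k in seq_along(programs)) {
    nm <- noise
    nm$seed <- as.integer((as.double(noise$seed) + k - 1) %% 2147483647)
    r <- render_sequence(scene, programs[[k]], nm, fps = fps)
    frames <- if (is.null(frames)) r$seq$frames
              else {
                d1 <- dim(frames); d2 <- dim(r$seq$frames)
                a <- array(0L, c(d1[1], d1[2], d1[3] + d2[3]))
                a[, , seq_len(d1[3])] <- frames
                a[, , d1[3] + seq_len(d2[3])] <- r$seq$frames
                a
              }
    ts <- c(ts, t0 + r$seq$timestamps)
    tv <- c(tv, r$truth$tv_L)
    pk <- c(pk, t0 + r$truth$peak_times_s)
    vt <- c(vt, t0 + r$truth$volume_t_s)
    vv <- c(vv, r$truth$volume_L)
    t0 <- ts[length(ts)] + 1 / fps
  }
  keep <- !duplicated(vt)
  truth <- structure(list(
    rr_bpm = vapply(programs, function(p) p$rr_bpm, numeric(1)),
    tv_L = tv, peak_times_s = pk,
    volume_t_s = vt[keep], volume_L = vv[keep],
    shoulders = scene$shoulders_true,
    chest_area_m2 = scene$chest_area_m2,
    abdomen_area_m2 = scene$abdomen_area_m2,
    duration_s = ts[length(ts)], fps = fps
  ), class = "torso_truth")
  list(seq = depth_sequence(frames, ts), truth = truth)
}

#' Synthetic reference (spirometer-style) trace
#'
#' Samples the ground-truth instantaneous volume on the reference
#' device's own clock, delayed so that the depth recording starts
#' `trigger_lag_s` after the reference recording; the trigger flag
#' rises at that instant.  Optional additive Gaussian volume noise.
#'
#' @param truth `torso_truth` from [render_sequence()].
#' @param sample_rate reference sampling rate, Hz (default 100; any
#'   uniform rate >= 25 is accepted downstream).
#' @param trigger_lag_s reference time at which the depth recording
#'   (and the trigger) starts.
#' @param volume_noise_L additive noise SD, litres.
#' @param seed RNG seed for the volume noise.
#' @return A [reference_trace()].
#' @export
synth_reference_trace <- function(truth, sample_rate = 100,
                                  trigger_lag_s = 0,
                                  volume_noise_L = 0, seed = 1L) {
  stopifnot_scalar_number(sample_rate, "sample_rate", min = 1)
  stopifnot_scalar_number(trigger_lag_s, "trigger_lag_s", min = 0)
  t_end <- trigger_lag_s + truth$duration_s
  tt <- seq(0, t_end, by = 1 / sample_rate)
  v <- approx(truth$volume_t_s + trigger_lag_s, truth$volume_L,
              xout = tt, rule = 2)$y
  if (volume_noise_L > 0)
    v <- v + with_seed(seed, rnorm(length(tt), sd = volume_noise_L))
  trig <- as.integer(tt >= trigger_lag_s - 1e-12)
  reference_trace(tt, v, trig)
}

#' Reproducible synthetic cohort
#'
#' Samples subject presets from sex-specific anthropometric priors:
#' chest circumference around 103.5 cm for males and 87.4 cm for
#' females (the ordering of the two strata follows published elderly
#' reference means), with quiet-breathing amplitudes and rates drawn
#' per subject and a deep-breathing run of five breaths at 2.5 x the
#' amplitude and 0.6 x the rate.  The within-stratum circumference SD
#' is kept at 3 cm so that pooled per-stratum calibration error
#' reflects the algorithm rather than population scale heterogeneity.
#'
#' @param n_subjects number of subjects (alternating strata).
#' @param strata character vector of stratum labels (default male,
#'   female).
#' @param noise a [noise_model()] shared by the cohort; each subject
#'   gets a distinct rendering seed derived from `seed`.
#' @param seed cohort RNG seed.
#' @param frame_height,frame_width rendered frame size for the cohort
#'   (default 212 x 256, half the sensor grid, for tractable volumes).
#' @param duration_normal_s quiet-breathing recording length.
#' @return List of subject presets, each a list with `id`, `stratum`,
#'   `scene`, `program_normal`, `program_deep`, `noise`.
#' @export
make_cohort <- function(n_subjects = 10, strata = c("male", "female"),
                        noise = noise_model(), seed = 1L,
                        frame_height = 212L, frame_width = 256L,
                        duration_normal_s = 40) {
  if (n_subjects < 1)
    abort_respdepth("validation", "n_subjects must be >= 1")
  circ_mean <- c(male = 103.5, female = 87.4)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      stratum <- strata[((i - 1) %% length(strata)) + 1]
      mu <- if (stratum %in% names(circ_mean)) circ_mean[[stratum]] else 95
      circ <- rnorm(1, mu, 3)
      scene <- torso_scene(frame_height = frame_height,
                           frame_width = frame_width,
                           chest_circumference_cm = circ)
      pn <- breathing_program("normal",
                              rr_bpm = runif(1, 10, 16),
                              chest_amp_mm = runif(1, 4, 6),
                              abdomen_amp_mm = runif(1, 3, 5),
                              duration_s = duration_normal_s)
      pd <- breathing_program("deep",
                              rr_bpm = pn$rr_bpm * 0.6,
                              chest_amp_mm = pn$chest_amp_mm * 2.5,
                              abdomen_amp_mm = pn$abdomen_amp_mm * 2.5,
                              n_breaths = 5)
      nm <- noise
      nm$seed <- as.integer((as.double(seed) * 1000 + i) %% 2147483647)
      list(id = i, stratum = stratum,
           chest_circumference_cm = circ,
           scene = scene, program_normal = pn, program_deep = pd,
           noise = nm)
    })
  })
}
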