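test_that("a zero-amplitude program renders a static scene", {
  sc <- torso_scene(100L, 120L)
  prog <- breathing_program("normal", chest_amp_mm = 0, abdomen_amp_mm = 0,
                            duration_s = 1)
  r <- render_sequence(sc, prog, noise_none(), fps = 5)
  for (k in 2:r$seq$n_frames)
    expect_identical(r$seq$frames[, , k], r$seq$frames[, , 1])
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- torso_scene(100L, 120L)
  prog <- breathing_program("normal", duration_s = 2)
  nm <- noise_model(seed = 99L)
  r1 <- render_sequence(sc, prog, nm, fps = 10)
  r2 <- render_sequence(sc, prog, nm, fps = 10)
  expect_identical(r1$seq$frames, r2$seq$frames)
  nm2 <- noise_model(seed = 100L)
  r3 <- render_sequence(sc, prog, nm2, fps = 10)
  expect_false(identical(r1$seq$frames, r3$seq$frames))
})

test_that("true tidal volume is area times piston displacement", {
  sc <- small_scene()
  prog <- breathing_program("normal", chest_amp_mm = 8, abdomen_amp_mm = 0,
                            rr_bpm = 12, duration_s = 10)
  r <- render_sequence(sc, prog, noise_none(), fps = 10)
  expect_equal(r$truth$tv_L[1], sc$chest_area_m2 * 8, tolerance = 1e-12)
  # instantaneous volume peaks match the analytic peak times
  expect_equal(r$truth$peak_times_s, c(2.5, 7.5))
})

test_that("the reference trace reproduces the ground truth volume", {
  sc <- small_scene()
  prog <- breathing_program("normal", rr_bpm = 12, duration_s = 20)
  r <- render_sequence(sc, prog, noise_none(), fps = 10)

  ref0 <- synth_reference_trace(r$truth, 100, trigger_lag_s = 0)
  expect_equal(ref0$trigger[1], 1L)
  expect_equal(align_by_trigger(r$seq, ref0), 0)

  # per-breath max - min of the sampled volume equals the true TV
  ref <- synth_reference_trace(r$truth, 100, trigger_lag_s = 0)
  for (k in 0:2) {
    i <- which(ref$time_s >= 5 * k & ref$time_s <= 5 * (k + 1))
    expect_equal(max(ref$volume_L[i]) - min(ref$volume_L[i]),
                 r$truth$tv_L[1], tolerance = 1e-9)
  }

  ref17 <- synth_reference_trace(r$truth, 100, trigger_lag_s = 1.7)
  expect_equal(align_by_trigger(r$seq, ref17), 1.7, tolerance = 0.011)
})

test_that("session rendering is continuous and merges ground truth", {
  sc <- small_scene()
  pn <- breathing_program("normal", rr_bpm = 15, duration_s = 12)
  pd <- breathing_program("deep", rr_bpm = 9, n_breaths = 2)
  s <- render_session(sc, list(pn, pd), noise_none(), fps = 10)
  expect_equal(s$seq$n_frames,
               (floor(12 * 10) + 1) + (floor(pd$duration_s * 10) + 1))
  expect_true(all(diff(s$seq$timestamps) > 0))
  expect_true(all(diff(s$truth$peak_times_s) > 0))
  expect_equal(length(s$truth$tv_L),
               length(s$truth$peak_times_s))
  # deep breaths displace 2.5 times the quiet volume
  expect_equal(max(s$truth$tv_L) / min(s$truth$tv_L), 2.5, tolerance = 1e-9)
})

test_that("cohorts are reproducible and follow the anthropometric ordering", {
  c1 <- make_cohort(10, seed = 5)
  c2 <- make_cohort(10, seed = 5)
  expect_equal(c1, c2)

  circ <- vapply(c1, function(s) s$chest_circumference_cm, numeric(1))
  sex <- vapply(c1, function(s) s$stratum, character(1))
  expect_gt(mean(circ[sex == "male"]), mean(circ[sex == "female"]))

  c3 <- make_cohort(1, seed = 5)
  expect_length(c3, 1)
  expect_s3_class(c3[[1]]$scene, "torso_scene")
})

test_that("anti-phase whole-body sway shrinks the estimated amplitude", {
  sc <- small_scene()
  prog <- breathing_program("normal", rr_bpm = 15, duration_s = 20)
  amp_with <- function(nm) {
    r <- render_sequence(sc, prog, nm, fps = 15)
    mean(run_estimate(r$seq)$breaths$amplitude_mm)
  }
  a0 <- amp_with(noise_none())
  a1 <- amp_with(noise_model(pixel_sd_mm = 0, dropout_prob = 0,
                             sway_amp_mm = 1, sway_period_s = 60 / 15,
                             sway_phase_deg = 90))
  expect_lt(a1, a0)
})

test_that("thoracoabdominal phase lag shrinks the summed excursion", {
  sc <- small_scene()
  amp_lag <- function(lag) {
    prog <- breathing_program("normal", rr_bpm = 15, phase_lag_deg = lag,
                              duration_s = 20)
    r <- render_sequence(sc, prog, noise_none(), fps = 15)
    mean(run_estimate(r$seq)$breaths$amplitude_mm)
  }
  expect_lt(amp_lag(90), amp_lag(0))
})

test_that("program and noise validation reject out-of-range parameters", {
  expect_respdepth_error(breathing_program("normal", rr_bpm = 50), "validation")
  expect_respdepth_error(breathing_program("normal", chest_amp_mm = -1),
                         "validation")
  expect_respdepth_error(breathing_program("normal", phase_lag_deg = 200),
                         "validation")
  expect_respdepth_error(noise_model(dropout_prob = 1.5), "validation")
  expect_respdepth_error(noise_model(pixel_sd_mm = -0.1), "validation")
})
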