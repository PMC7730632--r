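test_that("ROI mean signal is zero for a static scene and tracks approach", {
  seq <- flat_sequence(depth = 1500L, n = 5L)
  roi <- list(top = 2L, bottom = 30L, left = 2L, right = 25L, stage = "final")
  sig <- roi_mean_signal(seq, roi)
  expect_true(all(abs(sig$x) < 1e-9))

  # whole ROI moves 5 mm toward the camera -> x rises by 5
  fr <- array(1000L, c(40, 30, 3))
  fr[, , 2] <- 998L
  fr[, , 3] <- 995L
  sig2 <- roi_mean_signal(depth_sequence(fr, (0:2) / 30), roi)
  expect_equal(sig2$x[length(sig2$x)] - sig2$x[1], 5)

  fr[, , 2] <- 0L
  expect_respdepth_error(
    roi_mean_signal(depth_sequence(fr, (0:2) / 30), roi), "signal")
})

test_that("ROI mean matches a brute-force valid-pixel average on rendered frames", {
  r <- small_recording()
  est <- run_estimate(r$seq)
  roi <- est$roi_final
  sig <- roi_mean_signal(r$seq, roi, sample_rate = 15)  # native rate: no interp
  oracle <- vapply(seq_len(r$seq$n_frames), function(f) {
    block <- r$seq$frames[(roi$top + 1):roi$bottom,
                          (roi$left + 1):roi$right, f]
    mean(block[block > 0])
  }, numeric(1))
  oracle <- -(oracle - mean(oracle))
  n <- length(sig$x)
  expect_equal(sig$x, (oracle - mean(oracle[seq_len(n)]))[seq_len(n)],
               tolerance = 1e-9)
})

test_that("smoothing is zero phase, exact on constants and impulses", {
  t <- (0:99) / 30
  const <- resp_signal(t, rep(2.5, 100), 30)
  expect_equal(resp_smooth(const, 0.5)$x, rep(2.5, 100))

  imp <- numeric(100); imp[50] <- 1
  sm <- resp_smooth(resp_signal(t, imp, 30), 0.5)  # window 15
  expect_equal(sm$x[43:57], rep(1 / 15, 15), tolerance = 1e-12)
  expect_equal(sum(sm$x), 1, tolerance = 1e-12)
})

test_that("moving-average attenuation matches the Dirichlet kernel closed form", {
  f <- 0.2; rate <- 30; w <- 15
  t <- (0:3599) / rate
  sig <- resp_signal(t, sin(2 * pi * f * t), rate)
  sm <- resp_smooth(sig, w / rate)
  # regression on the quadrature basis, away from the shrinking edges
  i <- 200:3400
  X <- cbind(cos(2 * pi * f * t[i]), sin(2 * pi * f * t[i]))
  amp <- sqrt(sum(lm.fit(X, sm$x[i])$coefficients^2))
  dirichlet <- abs(sin(pi * f * w / rate) / (w * sin(pi * f / rate)))
  expect_equal(amp, dirichlet, tolerance = 1e-6)
})

test_that("a sinusoid segments into the expected breaths", {
  A <- 3; f <- 0.2
  ev <- detect_breaths(sine_signal(A, f, 60, 30))
  expect_gte(length(ev$peaks), 11)
  expect_lte(length(ev$peaks), 13)
  expect_true(all(abs(ev$amplitudes - 2 * A) <= 0.01 * 2 * A))
  expect_true(all(abs(ev$intervals - 5) <= 1 / 30 + 1e-9))

  # peaks and valleys strictly alternate (mandatory invariant)
  idx <- sort(c(ev$peaks, ev$valleys))
  expect_true(all(diff(idx %in% ev$peaks) != 0))

  ramp <- resp_signal((0:299) / 30, seq(0, 10, length.out = 300), 30)
  expect_respdepth_error(detect_breaths(ramp), "signal")
})

test_that("high-frequency jitter does not change the breath count", {
  rate <- 30; t <- seq(0, 60, by = 1 / rate)
  clean <- resp_signal(t, 3 * sin(2 * pi * 0.25 * t), rate)
  noisy <- resp_signal(t, 3 * sin(2 * pi * 0.25 * t) +
                          0.3 * sin(2 * pi * 2 * t), rate)
  ev_ref <- detect_breaths(clean)                     # oracle: clean component
  ev <- detect_breaths(resp_smooth(noisy, 0.5))
  expect_equal(length(ev$peaks), length(ev_ref$peaks))
})

test_that("events shift with time and scale with amplitude", {
  rate <- 30
  t1 <- seq(0, 40, by = 1 / rate)
  x <- 2 * sin(2 * pi * 0.25 * t1) + 1.5
  e1 <- detect_breaths(resp_signal(t1, x, rate))
  e2 <- detect_breaths(resp_signal(t1 + 100, x, rate))
  expect_equal(e2$peak_times_s, e1$peak_times_s + 100)
  expect_equal(e2$amplitudes, e1$amplitudes)

  e3 <- detect_breaths(resp_signal(t1, 3 * x, rate))
  expect_equal(e3$amplitudes, 3 * e1$amplitudes, tolerance = 1e-12)
  expect_equal(e3$intervals, e1$intervals)
})
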