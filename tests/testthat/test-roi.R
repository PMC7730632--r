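test_that("tentative ROI follows the shoulder geometry", {
  sh <- list(left = c(100L, 150L), right = c(110L, 350L))
  roi <- build_tentative_roi(sh, 424, 512, 30)
  expect_equal(roi[c("top", "left", "right", "bottom")],
               list(top = 110L, left = 180L, right = 320L, bottom = 424L))
  expect_equal(roi$stage, "tentative")

  roi0 <- build_tentative_roi(sh, 424, 512, 0)
  expect_equal(c(roi0$left, roi0$right), c(150L, 350L))

  sh2 <- list(left = c(100L, 150L), right = c(100L, 350L))
  expect_respdepth_error(build_tentative_roi(sh2, 424, 512, 120), "geometry")
})

test_that("unit grid counts match brute-force enumeration", {
  roi <- list(top = 0L, bottom = 100L, left = 0L, right = 100L,
              stage = "tentative")
  g <- build_unit_grid(roi, 19, 10)
  brute <- sum(sapply(0:99, function(k) k %% 10 == 0 && k + 19 <= 100))
  expect_equal(g$n_rows, brute)
  expect_equal(g$n_cols, brute)
  expect_equal(brute, 9)

  g1 <- build_unit_grid(list(top = 5L, bottom = 24L, left = 3L, right = 22L),
                        19, 10)
  expect_equal(c(g1$n_rows, g1$n_cols), c(1L, 1L))

  expect_respdepth_error(
    build_unit_grid(list(top = 0L, bottom = 18L, left = 0L, right = 50L),
                    19, 10), "geometry")
})

test_that("unit waveforms average valid pixels and flag dead units", {
  seq <- flat_sequence(depth = 1234L, n = 4L, h = 40L, w = 40L)
  g <- build_unit_grid(list(top = 0L, bottom = 40L, left = 0L, right = 40L))
  uw <- extract_unit_waveforms(seq, g, sample_rate = 30)
  expect_true(all(abs(uw$values - 1234) < 1e-9, na.rm = TRUE))
  expect_true(all(uw$validity))

  # mixed-depth unit: mean equals the brute-force block mean
  fr <- array(1000L, c(40, 40, 3))
  fr[, 21:40, ] <- 3000L
  seq2 <- depth_sequence(fr, (0:2) / 30)
  uw2 <- extract_unit_waveforms(seq2, g, 30)
  anchors_r <- g$row_tops[1] + (1:19)
  anchors_c <- g$col_lefts[2] + (1:19)   # unit straddling the boundary
  oracle <- mean(fr[anchors_r, anchors_c, 1])
  expect_equal(uw2$values[1, 2, 1], oracle)

  # unit with all pixels invalid in all frames -> flagged
  fr3 <- array(1000L, c(40, 40, 3))
  fr3[1:19, 1:19, ] <- 0L
  uw3 <- extract_unit_waveforms(depth_sequence(fr3, (0:2) / 30), g, 30)
  expect_false(uw3$validity[1, 1])
  expect_true(uw3$validity[2, 2])
})

make_units <- function(rows_mat, rate = 30) {
  # rows_mat: n_rows x n_samples, one unit column
  n <- ncol(rows_mat)
  list(values = array(rows_mat, c(nrow(rows_mat), 1, n)),
       validity = matrix(TRUE, nrow(rows_mat), 1),
       t = (seq_len(n) - 1) / rate, sample_rate = rate)
}

test_that("row amplitude ratios follow per-row excursions", {
  t <- (0:150) / 30
  base <- sin(2 * pi * 0.2 * t)
  u <- make_units(rbind(4 * base, 1 * base))
  rows <- compute_row_waveforms(u, list(c(1, 151)))
  expect_equal(rows$amplitude_ratio, c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(sum(rows$amplitude_ratio), 1, tolerance = 1e-9)

  u2 <- make_units(rbind(base, base, base, base))
  rows2 <- compute_row_waveforms(u2, list(c(1, 151)))
  expect_equal(rows2$amplitude_ratio, rep(0.25, 4), tolerance = 1e-9)
  expect_true(all(diff(rows2$cumulative_ratio) >= -1e-12))
  expect_equal(rows2$cumulative_ratio[4], 1, tolerance = 1e-9)

  expect_respdepth_error(compute_row_waveforms(u, list()), "signal")
})

test_that("amplitude ratios are invariant to uniform scaling", {
  t <- (0:200) / 30
  set.seed(11)
  sig <- rbind(3 * sin(2 * pi * 0.25 * t), 2 * sin(2 * pi * 0.25 * t),
               0.5 * sin(2 * pi * 0.25 * t))
  r1 <- compute_row_waveforms(make_units(sig), list(c(1, 121), c(121, 201)))
  r2 <- compute_row_waveforms(make_units(7.3 * sig),
                              list(c(1, 121), c(121, 201)))
  expect_equal(r1$amplitude_ratio, r2$amplitude_ratio, tolerance = 1e-12)
})

test_that("ROI bottom lands at the first cumulative-ratio crossing", {
  tent <- list(top = 0L, bottom = 100L, left = 0L, right = 40L,
               stage = "tentative")
  g <- build_unit_grid(tent, 19, 10)

  mk_rows <- function(amps) {
    ratio <- amps / sum(amps)
    list(row_index = seq_along(amps), row_amplitude = amps,
         amplitude_ratio = ratio, cumulative_ratio = cumsum(ratio))
  }
  # [4,3,2,1]: cumulative [0.4, 0.7, 0.9, 1.0] -> third row crosses 0.9
  roi <- finalize_roi(tent, mk_rows(c(4, 3, 2, 1)), g)
  expect_equal(attr(roi, "cut_row"), 3L)
  expect_equal(roi$bottom, g$row_tops[3] + 19L)
  expect_equal(roi$stage, "final")

  # single row
  roi1 <- finalize_roi(tent, mk_rows(5), g)
  expect_equal(attr(roi1, "cut_row"), 1L)

  # 10 equal rows: 9 x 0.1 attains 0.9 at the 9th row
  roi10 <- finalize_roi(tent, mk_rows(rep(1, 9)), g, cutoff = 0.90)
  expect_equal(attr(roi10, "cut_row"), 9L)
  rows10 <- mk_rows(rep(1, 10))
  g2 <- build_unit_grid(list(top = 0L, bottom = 120L, left = 0L,
                             right = 40L, stage = "tentative"), 19, 10)
  roi10b <- finalize_roi(tent, rows10, g2)
  expect_equal(attr(roi10b, "cut_row"), 9L)

  # final ROI nests inside the tentative one, sides unchanged
  expect_lte(roi$bottom, tent$bottom)
  expect_equal(roi[c("top", "left", "right")], tent[c("top", "left", "right")])
})

test_that("on the simulated torso the final ROI drops the static lap rows", {
  r <- small_recording()
  est <- run_estimate(r$seq)
  sc <- small_scene()
  # chest rows contribute more than abdomen rows
  prof <- est$row_profile
  chest_rows <- which(respdepth:::mask_bbox(sc$chest_mask)$top <=
                        (est$roi_tentative$top + 10 * (prof$grid_row - 1)) &
                      (est$roi_tentative$top + 10 * (prof$grid_row - 1)) <
                        respdepth:::mask_bbox(sc$chest_mask)$bottom)
  abd_bottom <- respdepth:::mask_bbox(sc$abdomen_mask)$bottom
  expect_lt(est$roi_final$bottom, sc$frame_height)     # not the image bottom
  expect_lte(est$roi_final$bottom, abd_bottom + 19)    # cut near abdomen end
  expect_gte(min(est$row_profile$cumulative_ratio[
    est$row_profile$cumulative_ratio >= 0.9]), 0.9)
})
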