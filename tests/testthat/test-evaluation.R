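breaths <- function(times, tv = NULL, rr = NULL) {
  out <- list(peak_time_s = times)
  if (!is.null(tv)) out$tv_L <- tv
  if (!is.null(rr)) out$rr_bpm <- rr
  out
}

test_that("breath matching pairs nearest peaks, each at most once", {
  tt <- seq(2, 47, by = 5)
  p <- match_breaths(breaths(tt), breaths(tt))
  expect_equal(nrow(p), length(tt))
  expect_true(all(p$match_dt_s == 0))

  p2 <- match_breaths(breaths(tt + 0.3), breaths(tt))
  expect_equal(p2$match_dt_s, rep(0.3, length(tt)))

  # est missing one breath: 9 matches, 1 reference breath unmatched;
  # greedy matching agrees with the (here unambiguous) optimal assignment
  p3 <- match_breaths(breaths(tt[-4]), breaths(tt))
  expect_equal(nrow(p3), 9)
  expect_equal(attr(p3, "n_unmatched_ref"), 1L)
  expect_equal(attr(p3, "n_unmatched_est"), 0L)
  expect_equal(p3$ref_idx, setdiff(seq_along(tt), 4))

  expect_respdepth_error(match_breaths(breaths(1), breaths(100)),
                         "evaluation")
})

test_that("MARE matches hand arithmetic", {
  expect_equal(mean_absolute_relative_error(c(0.9, 1.1), c(1, 1)), 10)
  expect_equal(mean_absolute_relative_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_absolute_relative_error(1.5, 1.0), 50)
  expect_respdepth_error(mean_absolute_relative_error(1, 0), "evaluation")

  # scaling behaviour from identity: est = c * ref -> MARE = 100|c - 1|
  ref <- c(0.4, 0.8, 1.3)
  expect_equal(mean_absolute_relative_error(1.15 * ref, ref), 15,
               tolerance = 1e-12)
})

test_that("Bland-Altman matches textbook formulas", {
  # identity: degenerate, collapsed CI
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_true(ba0$degenerate)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$ci, c(0, 0))
  expect_false(ba0$fixed_bias)

  # hand-computed three-pair case
  ba <- bland_altman(c(1.1, 1.2, 1.3), c(1, 1, 1))
  expect_equal(ba$bias, 0.2, tolerance = 1e-12)
  half <- qt(0.975, 2) * 0.1 / sqrt(3)
  expect_equal(ba$ci, c(0.2 - half, 0.2 + half), tolerance = 1e-12)
  expect_equal(ba$loa, c(0.2 - 1.96 * 0.1, 0.2 + 1.96 * 0.1),
               tolerance = 1e-12)
  # the wide small-n CI (0.2 +/- 0.248) still includes zero
  expect_false(ba$fixed_bias)
  # with more pairs at the same offset the CI tightens and bias is declared
  ba6 <- bland_altman(rep(c(1.1, 1.2, 1.3), 3), rep(1, 9))
  expect_true(ba6$fixed_bias)
})

test_that("proportional bias is detected and agrees with cor.test", {
  set.seed(33)
  ref <- runif(100, 0.4, 2)
  est <- ref + 0.1 * ref + rnorm(100, sd = 0.05)
  ba <- bland_altman(est, ref)
  ct <- cor.test(est - ref, (est + ref) / 2)
  expect_equal(ba$prop_bias_r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(ba$prop_bias_p, ct$p.value, tolerance = 1e-9)
  expect_true(ba$prop_bias)
  expect_lt(ba$prop_bias_p, 0.05)
})

test_that("Bland-Altman is antisymmetric under swapping the methods", {
  set.seed(34)
  a <- runif(12, 0.5, 2); b <- a + rnorm(12, 0.05, 0.1)
  ba <- bland_altman(a, b)
  ab <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ab$ci, rev(-ba$ci), tolerance = 1e-12)
  expect_equal(ab$loa, rev(-ba$loa), tolerance = 1e-12)
  expect_equal(ab$prop_bias_r, -ba$prop_bias_r, tolerance = 1e-12)
  expect_equal(ab$prop_bias_p, ba$prop_bias_p, tolerance = 1e-12)
})

test_that("RR errors use a strict threshold", {
  expect_equal(unname(rr_error_count(15.5, 14.2)), c(1, 1))
  expect_equal(unname(rr_error_count(15, 14)), c(0, 1))  # exactly 1: no error
  expect_equal(unname(rr_error_count(rep(12, 20), rep(12, 20))), c(0, 20))
})

test_that("the agreement statistics match an independent brute-force oracle", {
  set.seed(55)
  n <- 17
  ref <- runif(n, 0.3, 2.2)
  est <- ref * (1 + rnorm(n, 0, 0.12)) + 0.03
  rr_ref <- runif(n, 8, 22)
  rr_est <- rr_ref + rnorm(n, 0, 0.8)

  # oracle: plain-sum implementations of the textbook formulas
  d <- est - ref; m <- (est + ref) / 2
  o_mare <- 100 * sum(abs(d) / ref) / n
  o_bias <- sum(d) / n
  o_sd <- sqrt(sum((d - o_bias)^2) / (n - 1))
  o_ci <- o_bias + c(-1, 1) * qt(0.975, n - 1) * o_sd / sqrt(n)
  o_loa <- o_bias + c(-1, 1) * 1.96 * o_sd
  mc <- m - sum(m) / n; dc <- d - o_bias
  o_r <- sum(dc * mc) / sqrt(sum(dc^2) * sum(mc^2))
  o_t <- o_r * sqrt((n - 2) / (1 - o_r^2))
  o_p <- 2 * pt(-abs(o_t), n - 2)
  o_err <- sum(abs(rr_est - rr_ref) > 1)

  pairs <- match_breaths(breaths(seq_len(n) * 5, est, rr_est),
                         breaths(seq_len(n) * 5, ref, rr_ref))
  rep <- agreement_report(pairs)
  expect_equal(rep$mare_pct, o_mare, tolerance = 1e-9)
  expect_equal(rep$bias_L, o_bias, tolerance = 1e-9)
  expect_equal(rep$bias_ci_L, o_ci, tolerance = 1e-9)
  expect_equal(rep$loa_L, o_loa, tolerance = 1e-9)
  expect_equal(rep$prop_bias_r, o_r, tolerance = 1e-9)
  expect_equal(rep$prop_bias_p, o_p, tolerance = 1e-9)
  expect_equal(rep$rr_errors, o_err)
  expect_equal(rep$rr_total, n)
})
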