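#' Pair estimated and reference breaths by peak time
#'
#' Greedy nearest-peak-time matching: candidate pairs within
#' `window_s` are accepted in order of increasing absolute time offset,
#' each breath used at most once.  Unmatched breaths on either side are
#' counted, not dropped silently.  Both inputs must be on the same
#' clock (align the reference with [align_by_trigger()] first).
#'
#' @param est,ref lists (or data.frames) with `peak_time_s` and
#'   optionally `tv_L` and `rr_bpm` per breath.
#' @param window_s maximum |time offset| for a match (default 2 s).
#' @return A `data.frame` of class `breath_pairs` with columns
#'   `est_idx`, `ref_idx`, `match_dt_s`, and any of `est_tv_L`,
#'   `ref_tv_L`, `est_rr_bpm`, `ref_rr_bpm` available; attributes
#'   `n_unmatched_est`, `n_unmatched_ref`.
#' @export
match_breaths <- function(est, ref, window_s = 2.0) {
  te <- est$peak_time_s; tr <- ref$peak_time_s
  if (length(te) == 0L || length(tr) == 0L)
    abort_respdepth("evaluation", "no breaths to match")
  cand <- expand.grid(i = seq_along(te), j = seq_along(tr))
  cand$dt <- te[cand$i] - tr[cand$j]
  cand <- cand[abs(cand$dt) <= window_s, , drop = FALSE]
  cand <- cand[order(abs(cand$dt), cand$i, cand$j), , drop = FALSE]
  used_e <- logical(length(te)); used_r <- logical(length(tr))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_e[i] && !used_r[j]) {
      used_e[i] <- TRUE; used_r[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j, cand$dt[k])
    }
  }
  if (length(pairs) == 0L)
    abort_respdepth("evaluation", "zero matched breaths within the window")
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- data.frame(est_idx = m[, 1], ref_idx = m[, 2], match_dt_s = m[, 3])
  for (fld in c("tv_L", "rr_bpm")) {
    if (!is.null(est[[fld]])) out[[paste0("est_", fld)]] <- est[[fld]][out$est_idx]
    if (!is.null(ref[[fld]])) out[[paste0("ref_", fld)]] <- ref[[fld]][out$ref_idx]
  }
  attr(out, "n_unmatched_est") <- sum(!used_e)
  attr(out, "n_unmatched_ref") <- sum(!used_r)
  class(out) <- c("breath_pairs", "data.frame")
  out
}

#' Mean absolute relative error, percent
#'
#' `100 * mean(|est - ref| / ref)`; every reference value must be
#' strictly positive.
#'
#' @param est,ref numeric vectors of equal length.
#' @return Scalar percentage.
#' @export
mean_absolute_relative_error <- function(est, ref) {
  if (length(est) != length(ref))
    abort_respdepth("validation", "`est` and `ref` lengths differ")
  if (length(ref) == 0L || any(!is.finite(ref)) || any(ref <= 0))
    abort_respdepth("evaluation",
                    "reference values must be positive for a relative error")
  100 * mean(abs(est - ref) / ref)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences `d = est - ref` are summarised by their mean
#' (fixed bias) with a t-based 95 % confidence interval, the classical
#' limits of agreement `bias +/- 1.96 * SD(d)`, and the Pearson
#' correlation of `d` with the pair means (proportional bias), tested
#' two-sided at level `alpha`.  Fixed bias is declared when the CI
#' excludes zero; proportional bias when `p < alpha`.
#'
#' @param est,ref numeric vectors of equal length (>= 3 pairs).
#' @param alpha significance level (default 0.05).
#' @return Object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `ci` (length 2), `loa` (length 2), `prop_bias_r`, `prop_bias_p`,
#'   `fixed_bias`, `prop_bias`, `degenerate`, plus per-pair `mean_` and
#'   `diff_` for plotting.
#' @export
bland_altman <- function(est, ref, alpha = 0.05) {
  if (length(est) != length(ref))
    abort_respdepth("validation", "`est` and `ref` lengths differ")
  n <- length(est)
  if (n < 3L)
    abort_respdepth("evaluation", "Bland-Altman needs at least 3 pairs")
  d <- est - ref
  m <- (est + ref) / 2
  bias <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  if (degenerate) {
    ci <- c(bias, bias)
  } else {
    half <- qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
    ci <- c(bias - half, bias + half)
  }
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  if (degenerate || sd(m) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    r <- sum((d - mean(d)) * (m - mean(m))) /
      sqrt(sum((d - mean(d))^2) * sum((m - mean(m))^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(n = n, bias = bias, sd_diff = s, ci = ci, loa = loa,
                 prop_bias_r = r, prop_bias_p = p,
                 fixed_bias = !degenerate && (ci[1] > 0 || ci[2] < 0),
                 prop_bias = !is.na(p) && p < alpha,
                 degenerate = degenerate, alpha = alpha,
                 mean_ = m, diff_ = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman analysis\n")
  cat(sprintf("  n = %d pairs\n", x$n))
  cat(sprintf("  bias %.4f (95%% CI %.4f to %.4f)%s\n", x$bias,
              x$ci[1], x$ci[2],
              if (x$degenerate) " [degenerate: zero SD]" else ""))
  cat(sprintf("  limits of agreement %.4f to %.4f\n", x$loa[1], x$loa[2]))
  cat(sprintf("  proportional bias: r = %.4f, p = %.4g (%s)\n",
              x$prop_bias_r, x$prop_bias_p,
              if (isTRUE(x$prop_bias)) "present" else "absent"))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$mean_, x$diff_, xlab = "pair mean", ylab = "difference (est - ref)",
       main = "Bland-Altman", ...)
  abline(h = x$bias, col = "red3")
  abline(h = x$loa, col = "red3", lty = 2)
  abline(h = 0, col = "grey60")
  invisible(x)
}

#' Count respiratory-rate errors
#'
#' A breath counts as an RR error when the absolute difference between
#' the paired rates strictly exceeds the threshold (a difference of
#' exactly the threshold is not an error).
#'
#' @param est_rr,ref_rr paired rates, BPM.
#' @param threshold_bpm error threshold (default 1 BPM).
#' @return `c(errors = ..., total = ...)`.
#' @export
rr_error_count <- function(est_rr, ref_rr, threshold_bpm = 1.0) {
  if (length(est_rr) != length(ref_rr))
    abort_respdepth("validation", "`est_rr` and `ref_rr` lengths differ")
  if (length(est_rr) == 0L)
    abort_respdepth("evaluation", "no paired rates")
  c(errors = sum(abs(est_rr - ref_rr) > threshold_bpm),
    total = length(est_rr))
}

#' Full agreement report for a set of matched breaths
#'
#' Combines the mean absolute relative error of TV, the Bland-Altman
#' bias analysis of TV, and the RR error count into one object.
#'
#' @param pairs a [match_breaths()] result carrying TV and RR columns.
#' @param alpha significance level for the bias tests.
#' @param rr_threshold_bpm RR error threshold, BPM.
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, alpha = 0.05, rr_threshold_bpm = 1.0) {
  if (!all(c("est_tv_L", "ref_tv_L") %in% names(pairs)))
    abort_respdepth("evaluation", "pairs lack TV columns")
  ba <- bland_altman(pairs$est_tv_L, pairs$ref_tv_L, alpha = alpha)
  rr <- if (all(c("est_rr_bpm", "ref_rr_bpm") %in% names(pairs))) {
    ok <- is.finite(pairs$est_rr_bpm) & is.finite(pairs$ref_rr_bpm)
    if (any(ok))
      rr_error_count(pairs$est_rr_bpm[ok], pairs$ref_rr_bpm[ok],
                     rr_threshold_bpm)
    else c(errors = NA_integer_, total = 0L)
  } else c(errors = NA_integer_, total = 0L)
  structure(list(
    mare_pct = mean_absolute_relative_error(pairs$est_tv_L, pairs$ref_tv_L),
    bias_L = ba$bias, bias_ci_L = ba$ci, loa_L = ba$loa,
    prop_bias_r = ba$prop_bias_r, prop_bias_p = ba$prop_bias_p,
    fixed_bias = ba$fixed_bias, prop_bias = ba$prop_bias,
    rr_errors = unname(rr["errors"]), rr_total = unname(rr["total"]),
    n_pairs = nrow(pairs),
    n_unmatched_est = attr(pairs, "n_unmatched_est"),
    n_unmatched_ref = attr(pairs, "n_unmatched_ref"),
    bland_altman = ba
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report\n")
  cat(sprintf("  matched breaths      : %d (unmatched est %d, ref %d)\n",
              x$n_pairs, x$n_unmatched_est, x$n_unmatched_ref))
  cat(sprintf("  TV MARE              : %.2f %%\n", x$mare_pct))
  cat(sprintf("  TV bias              : %.4f L (95%% CI %.4f to %.4f) -> %s\n",
              x$bias_L, x$bias_ci_L[1], x$bias_ci_L[2],
              if (isTRUE(x$fixed_bias)) "fixed bias" else "no fixed bias"))
  cat(sprintf("  limits of agreement  : %.4f to %.4f L\n",
              x$loa_L[1], x$loa_L[2]))
  cat(sprintf("  proportional bias    : r = %.3f, p = %.3g -> %s\n",
              x$prop_bias_r, x$prop_bias_p,
              if (isTRUE(x$prop_bias)) "present" else "absent"))
  cat(sprintf("  RR errors (>1 BPM)   : %s / %s breaths\n",
              x$rr_errors, x$rr_total))
  invisible(x)
}

#' Write an agreement report (JSON + per-pair CSV)
#'
#' @param report an [agreement_report()].
#' @param path output JSON path; a sibling `<path>_pairs.csv` with the
#'   Bland-Altman scatter data (pair mean, difference) is written too.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  obj <- report[c("mare_pct", "bias_L", "bias_ci_L", "loa_L",
                  "prop_bias_r", "prop_bias_p", "fixed_bias", "prop_bias",
                  "rr_errors", "rr_total", "n_pairs",
                  "n_unmatched_est", "n_unmatched_ref")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  csv <- paste0(tools::file_path_sans_ext(path), "_pairs.csv")
  write.csv(data.frame(mean = report$bland_altman$mean_,
                       difference = report$bland_altman$diff_),
            csv, row.names = FALSE)
  invisible(path)
}
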