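#' Fit the amplitude-to-tidal-volume calibration
#'
#' Single linear regression with the reference (spirometer) tidal volume
#' as the response and the depth-camera per-breath displacement
#' amplitude as the explanatory variable.  One model is typically
#' fitted per stratum (e.g. sex by clothing condition); both quiet and
#' deep breaths enter the same regression.
#'
#' @param amplitudes_mm per-breath depth amplitudes, mm.
#' @param tv_ref_L matching reference tidal volumes, litres.
#' @param label stratum label stored with the model.
#' @param intercept include an intercept (default `TRUE`); with
#'   `FALSE` the line is forced through the origin.
#' @return Object of class `tv_calibration` with fields `slope` (L/mm),
#'   `intercept` (L), `r_squared`, `n`, `label`, and the training data.
#' @export
fit_calibration <- function(amplitudes_mm, tv_ref_L, label = "pooled",
                            intercept = TRUE) {
  a <- as.numeric(amplitudes_mm); v <- as.numeric(tv_ref_L)
  if (length(a) != length(v))
    abort_respdepth("validation", "amplitude and volume lengths differ")
  if (length(a) < 2L)
    abort_respdepth("fit", "at least 2 breaths are needed for calibration")
  if (any(!is.finite(a)) || any(!is.finite(v)))
    abort_respdepth("validation", "non-finite calibration data")
  if (var(a) == 0)
    abort_respdepth("fit", "zero amplitude variance: regression undefined")
  fit <- if (intercept) lm(v ~ a) else lm(v ~ 0 + a)
  cf <- coef(fit)
  slope <- unname(if (intercept) cf["a"] else cf["a"])
  intc <- unname(if (intercept) cf["(Intercept)"] else 0)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intc, r_squared = r2,
                 n = length(a), label = label,
                 has_intercept = isTRUE(intercept),
                 amplitudes_mm = a, tv_ref_L = v,
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "tv_calibration")
}

#' @export
print.tv_calibration <- function(x, ...) {
  cat("Tidal-volume calibration (single linear regression)\n")
  cat(sprintf("  stratum : %s\n", x$label))
  cat(sprintf("  TV [L] = %.4f * amplitude [mm] %+.4f\n", x$slope, x$intercept))
  cat(sprintf("  r-squared = %.4f on n = %d breaths\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
summary.tv_calibration <- function(object, ...) {
  out <- object[c("slope", "intercept", "r_squared", "n", "label")]
  out$rmse_L <- sqrt(mean(object$residuals^2))
  class(out) <- "summary.tv_calibration"
  out
}

#' @export
print.summary.tv_calibration <- function(x, ...) {
  cat(sprintf(paste0("tv_calibration [%s]: slope %.4f L/mm, intercept ",
                     "%.4f L, r2 %.4f, RMSE %.4f L, n %d\n"),
              x$label, x$slope, x$intercept, x$r_squared, x$rmse_L, x$n))
  invisible(x)
}

#' @export
coef.tv_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.tv_calibration <- function(object, ...) object$residuals

#' @export
predict.tv_calibration <- function(object, newdata = NULL, clip = TRUE, ...) {
  a <- if (is.null(newdata)) object$amplitudes_mm else as.numeric(newdata)
  estimate_tv(object, a, clip = clip)
}

#' @export
plot.tv_calibration <- function(x, ...) {
  plot(x$amplitudes_mm, x$tv_ref_L,
       xlab = "depth amplitude (mm)", ylab = "reference TV (L)",
       main = sprintf("TV calibration [%s]", x$label), ...)
  abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Per-breath tidal volume from a fitted calibration
#'
#' Applies `tv = slope * amplitude + intercept`.  Negative predictions
#' are unphysical and, with `clip = TRUE`, are set to zero; the number
#' of clipped breaths is returned in the `n_clipped` attribute and a
#' warning is raised.
#'
#' @param model a [fit_calibration()] model.
#' @param amplitudes_mm per-breath amplitudes, mm.
#' @param clip clip negative volumes at zero (default `TRUE`).
#' @return Numeric vector of TV estimates, litres, with attribute
#'   `n_clipped`.
#' @export
estimate_tv <- function(model, amplitudes_mm, clip = TRUE) {
  if (!inherits(model, "tv_calibration"))
    abort_respdepth("validation", "`model` must be a tv_calibration")
  tv <- model$slope * as.numeric(amplitudes_mm) + model$intercept
  n_clipped <- 0L
  if (clip && any(tv < 0)) {
    n_clipped <- sum(tv < 0)
    warning(sprintf("%d negative TV estimate(s) clipped to 0", n_clipped),
            call. = FALSE)
    tv[tv < 0] <- 0
  }
  attr(tv, "n_clipped") <- n_clipped
  tv
}

#' Per-breath respiratory rate from peak intervals
#'
#' Each breath's rate is the reciprocal of its peak-to-peak interval:
#' `rr = 60 / interval`, in breaths per minute.  The i-th rate is
#' anchored at the peak closing the interval.
#'
#' @param events a [detect_breaths()] result.
#' @return Numeric vector of rates, BPM, length `length(peaks) - 1`,
#'   with attribute `peak_times_s` (times of the closing peaks).
#' @export
estimate_rr <- function(events) {
  if (!inherits(events, "breath_events"))
    abort_respdepth("validation", "`events` must be breath_events")
  if (length(events$peaks) < 2L)
    abort_respdepth("signal", "at least 2 peaks are needed for RR")
  rr <- 60 / events$intervals
  attr(rr, "peak_times_s") <- events$peak_times_s[-1L]
  rr
}

#' Serialize a calibration model to JSON
#'
#' @param model a `tv_calibration`.
#' @param path output file.
#' @param config optional [resp_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path, config = NULL) {
  obj <- list(slope = model$slope, intercept = model$intercept,
              r_squared = model$r_squared, n = model$n,
              label = model$label, has_intercept = model$has_intercept)
  if (!is.null(config)) obj$config <- unclass(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path file written by [write_calibration()].
#' @return A `tv_calibration` (without training data).
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    abort_respdepth("format", sprintf("no such file: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("slope", "intercept", "n", "label")
  if (!all(need %in% names(obj)))
    abort_respdepth("format", "not a calibration model file")
  structure(list(slope = obj$slope, intercept = obj$intercept,
                 r_squared = obj$r_squared, n = obj$n, label = obj$label,
                 has_intercept = isTRUE(obj$has_intercept),
                 amplitudes_mm = numeric(0), tv_ref_L = numeric(0),
                 fitted = numeric(0), residuals = numeric(0)),
            class = "tv_calibration")
}
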