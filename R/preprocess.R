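#' Isosbestic regression of the control channel onto the signal channel
#'
#' Ordinary least-squares linear fit mapping the 405 nm control channel onto
#' the 470 nm signal channel; the fitted control serves as the baseline
#' `F0(t)` for dF/F0 normalization. The closed-form simple-regression
#' solution (`slope = cov(control, signal) / var(control)`) is used; it is
#' the exact normal-equation OLS estimate.
#'
#' @param control Control-channel samples (405 nm), or a [raw_trace()].
#' @param signal Signal-channel samples (470 nm); ignored when `control` is
#'   a `raw_trace`.
#' @return An object of class `isosbestic_fit` with `coef`, `predict`,
#'   `residuals` and `print` methods; fields `slope`, `intercept`,
#'   `residual_sd`.
#' @examples
#' x <- 100 + sin(seq(0, 10, 0.01))
#' f <- fit_isosbestic(x, 2 * x + 1)
#' coef(f)  # intercept 1, slope 2
#' @export
fit_isosbestic <- function(control, signal = NULL) {
  if (inherits(control, "raw_trace")) {
    signal <- control$f_signal
    control <- control$f_control
  }
  if (length(control) != length(signal))
    stopf("control and signal must have equal length")
  if (length(control) < 2) stopf("need at least 2 samples to fit")
  vx <- var(control)
  if (!is.finite(vx) || vx == 0)
    stopf("degenerate fit: control channel has zero variance")
  slope <- cov(control, signal) / vx
  intercept <- mean(signal) - slope * mean(control)
  res <- signal - (intercept + slope * control)
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = if (length(res) > 2) sd(res) else 0,
                 n = length(control)),
            class = "isosbestic_fit")
}

#' @export
coef.isosbestic_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.isosbestic_fit <- function(object, control, ...) {
  object$intercept + object$slope * control
}

#' @export
residuals.isosbestic_fit <- function(object, control, signal, ...) {
  signal - predict(object, control)
}

#' @export
print.isosbestic_fit <- function(x, ...) {
  cat(sprintf("Isosbestic fit (n = %d): F0 = %.6g + %.6g * F405 (residual sd %.3g)\n",
              x$n, x$intercept, x$slope, x$residual_sd))
  invisible(x)
}

#' dF/F0 trace
#'
#' Normalized fluorescence `(F(t) - F0(t)) / F0(t)` with `F(t)` the raw
#' signal channel and `F0(t)` the fitted control channel.
#'
#' @param t Time grid, seconds.
#' @param dff dF/F0 samples.
#' @param fs Sampling rate, Hz.
#' @param fit The [fit_isosbestic()] used (provenance), or `NULL`.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(t, dff, fs, fit = NULL) {
  if (length(t) != length(dff)) stopf("dff_trace: t and dff lengths differ")
  if (any(!is.finite(dff))) stopf("dff_trace: dff must be finite everywhere")
  structure(list(t = t, dff = dff, fs = fs, fit = fit), class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dff_trace: %d samples at %g Hz; dF/F0 range [%.4f, %.4f]\n",
              length(x$t), x$fs, min(x$dff), max(x$dff)))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, ...) {
  plot(x$t, x$dff, type = "l", xlab = "time (s)", ylab = expression(Delta * F / F[0]),
       ...)
  abline(h = 0, col = "grey60", lty = 2)
  invisible(x)
}

#' Isosbestic-corrected dF/F0 normalization
#'
#' Computes `dff(t) = (f_signal(t) - F0(t)) / F0(t)` with
#' `F0(t) = slope * f_control(t) + intercept` from an isosbestic fit
#' (computed over the full recording when not supplied).
#'
#' @param raw A [raw_trace()].
#' @param fit Optional precomputed [fit_isosbestic()].
#' @return A [dff_trace()] carrying the fit as provenance.
#' @examples
#' sim <- simulate_traces(generate_schedule(task_config(), seed = 1),
#'                        region_kernel("NAc_dopamine"), seed = 1)
#' dff <- compute_dff(sim$trace)
#' @export
compute_dff <- function(raw, fit = NULL) {
  if (!inherits(raw, "raw_trace")) stopf("`raw` must be a raw_trace")
  if (is.null(fit)) fit <- fit_isosbestic(raw)
  f0 <- predict(fit, raw$f_control)
  bad <- which(f0 <= 0)
  if (length(bad))
    stopf("fitted F0 non-positive over t = %.2f..%.2f s (%d samples); cannot divide",
          raw$t[min(bad)], raw$t[max(bad)], length(bad))
  dff_trace(raw$t, (raw$f_signal - f0) / f0, raw$fs, fit)
}

#' Zero-phase low-pass filter of a dF/F0 trace
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and unit DC gain so event
#' latencies used by the kinetics analysis are preserved.
#'
#' @param trace A [dff_trace()].
#' @param cutoff_hz Cutoff frequency; must satisfy `0 < cutoff_hz < fs / 2`.
#' @return The filtered [dff_trace()].
#' @export
lowpass_dff <- function(trace, cutoff_hz) {
  if (!inherits(trace, "dff_trace")) stopf("`trace` must be a dff_trace")
  if (!is_scalar_num(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= trace$fs / 2)
    stopf("`cutoff_hz` must lie in (0, fs/2) = (0, %g)", trace$fs / 2)
  bf <- signal::butter(2, cutoff_hz / (trace$fs / 2), type = "low")
  # reflect-pad to suppress filtfilt edge transients (keeps DC gain exact)
  x <- trace$dff
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * trace$fs / cutoff_hz))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  dff_trace(trace$t, y, trace$fs, trace$fit)
}
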