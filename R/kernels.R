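#' Transient response kernel
#'
#' The unit-amplitude transient used throughout the simulator:
#' `k(t) = (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)` for `t >= 0`,
#' zero before the event. Its maximum sits at
#' `tau_rise * log(1 + tau_decay / tau_rise)` ([kernel_peak_time()]).
#'
#' @param t Times relative to the event, seconds (vector).
#' @param tau_rise_s Rise time constant, seconds (> 0).
#' @param tau_decay_s Decay time constant, seconds (> `tau_rise_s`).
#' @return Kernel values at `t` (peak value < 1).
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' k <- transient_kernel(t, 0.6, 2.5)
#' t[which.max(k)]  # ~ kernel_peak_time(0.6, 2.5)
#' @export
transient_kernel <- function(t, tau_rise_s, tau_decay_s) {
  check_taus(tau_rise_s, tau_decay_s)
  k <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  k[pos] <- (1 - exp(-tp / tau_rise_s)) * exp(-tp / tau_decay_s)
  k
}

check_taus <- function(tau_rise_s, tau_decay_s) {
  if (!is_scalar_num(tau_rise_s) || tau_rise_s <= 0)
    stopf("`tau_rise_s` must be > 0")
  if (!is_scalar_num(tau_decay_s) || tau_decay_s <= tau_rise_s)
    stopf("`tau_decay_s` must exceed `tau_rise_s`")
  invisible(NULL)
}

#' @rdname transient_kernel
#' @export
kernel_peak_time <- function(tau_rise_s, tau_decay_s) {
  check_taus(tau_rise_s, tau_decay_s)
  tau_rise_s * log(1 + tau_decay_s / tau_rise_s)
}

#' Closed-form windowed integral of the transient kernel
#'
#' `integral over [lo, hi] of (1 - exp(-t/tau_r)) exp(-t/tau_d) dt`, used as
#' the analytic reference for trapezoidal AUC estimates.
#'
#' @inheritParams transient_kernel
#' @param lo,hi Integration bounds in seconds (clipped below at 0).
#' @return The integral in kernel-units times seconds.
#' @export
kernel_window_integral <- function(tau_rise_s, tau_decay_s, lo, hi) {
  check_taus(tau_rise_s, tau_decay_s)
  lo <- max(lo, 0)
  if (hi <= lo) return(0)
  a <- 1 / tau_decay_s
  b <- 1 / tau_rise_s + 1 / tau_decay_s
  prim <- function(t) -exp(-a * t) / a + exp(-b * t) / b
  prim(hi) - prim(lo)
}

#' Region-specific kernel parameters
#'
#' Kinetic presets for the transient kernel. The decay ordering
#' `LH_dopamine < NAc_dopamine < LH_orexin` encodes the empirical picture:
#' hypothalamic dopamine transients are fast and plateau during a 5 s
#' stimulation; accumbal dopamine keeps rising until the laser stops and
#' peaks just after stimulation offset; orexin-GCaMP6s responses are slow
#' and sustained. The preset values are simulator defaults, not measured
#' constants.
#'
#' Each preset carries two kinetic regimes. The full
#' `tau_rise_s`/`tau_decay_s` pair describes the response to a 5 s
#' stimulation train — a sustained deflection that, in the accumbens,
#' keeps rising until just after the train ends, while in the hypothalamus
#' it plateaus early. Cue-evoked transients are brief phasic events
#' (`cue_tau_rise_s`/`cue_tau_decay_s`, sub-second decay for dopamine),
#' which is why the cue-response AUC window is 0--1.5 s and why the signal
#' has returned to baseline by the time the predicted laser would arrive.
#'
#' @param tau_rise_s,tau_decay_s Kernel time constants of the stimulation
#'   response, seconds.
#' @param cue_tau_rise_s,cue_tau_decay_s Time constants of the phasic
#'   cue-evoked transient, seconds.
#' @param amplitude Reference amplitude in dF/F units (per-event amplitudes
#'   come from the ground truth; this is carried as metadata).
#' @param region_label One of `"NAc_dopamine"`, `"LH_dopamine"`,
#'   `"LH_orexin"`, or a free label for custom kernels.
#' @return An object of class `kernel_params`.
#' @examples
#' region_kernel("LH_dopamine")
#' @export
kernel_params <- function(tau_rise_s, tau_decay_s,
                          cue_tau_rise_s = 0.2 * tau_rise_s,
                          cue_tau_decay_s = 0.2 * tau_decay_s,
                          amplitude = 1, region_label = "custom") {
  check_taus(tau_rise_s, tau_decay_s)
  check_taus(cue_tau_rise_s, cue_tau_decay_s)
  structure(list(tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 cue_tau_rise_s = cue_tau_rise_s,
                 cue_tau_decay_s = cue_tau_decay_s,
                 amplitude = amplitude, region_label = region_label),
            class = "kernel_params")
}

#' @rdname kernel_params
#' @param region Preset name.
#' @export
region_kernel <- function(region = c("NAc_dopamine", "LH_dopamine", "LH_orexin")) {
  region <- match.arg(region)
  presets <- list(
    # stim peak ~5.2 s after onset: keeps rising through a 5 s train;
    # phasic cue transient decays within ~1.5 s
    NAc_dopamine = c(3.5, 12, 0.15, 0.5),
    # stim peak ~1.0 s: plateaus during the train; slightly faster transient
    LH_dopamine = c(0.6, 2.5, 0.12, 0.4),
    # slow, sustained GCaMP6s responses for both regimes
    LH_orexin = c(1.5, 20, 0.5, 2.5)
  )
  p <- presets[[region]]
  kernel_params(p[1], p[2], p[3], p[4], region_label = region)
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("Transient kernel [%s]: stim tau %g/%g s (peak %.3f s); cue tau %g/%g s (peak %.3f s)\n",
              x$region_label, x$tau_rise_s, x$tau_decay_s,
              kernel_peak_time(x$tau_rise_s, x$tau_decay_s),
              x$cue_tau_rise_s, x$cue_tau_decay_s,
              kernel_peak_time(x$cue_tau_rise_s, x$cue_tau_decay_s)))
  invisible(x)
}
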