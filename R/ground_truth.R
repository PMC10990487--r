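#' Ground-truth generative parameters for synthetic recordings
#'
#' Collects every free parameter of the forward model: the saturating
#' learning curve of the cue response, the stimulation-evoked and omission
#' dip amplitudes, the tonic baseline (a detectable basal sensor signal on
#' top of which the dip rides), artifact parameters (double-exponential
#' bleaching, shared low-frequency motion noise, per-channel white noise)
#' and the multiplicative condition scale (drug/anesthesia attenuation).
#'
#' Amplitudes are in dF/F units. Defaults are chosen to look like a typical
#' dLight recording: ~5% asymptotic cue transients, ~10% direct stimulation
#' transients, a -3% omission dip on a 10% tonic level, 0.3% white channel
#' noise and 1% motion artifact.
#'
#' @param a_max Asymptotic learned cue-response amplitude (`A(s) =
#'   a_max * (1 - exp(-s / learning_rate_sessions))`).
#' @param learning_rate_sessions Learning time constant in sessions.
#' @param nonlaser_amplitude Constant (small) response to the non-laser cue.
#' @param stim_amplitude Response amplitude at laser onset on stimulated
#'   trials.
#' @param dip_amplitude Omission dip amplitude; must be <= 0.
#' @param dip_tau_rise_s,dip_tau_decay_s Time constants of the dip kernel,
#'   seconds; the dip tracks tonic-dopamine clearance and is slower than
#'   the phasic cue transient.
#' @param tonic Tonic baseline signal level (dimensionless, >= 0).
#' @param condition_scale Multiplicative scale in `[0, 1]` applied to every
#'   response amplitude (1 = untreated).
#' @param noise_sd Per-channel iid Gaussian noise sd, as a fraction of the
#'   channel gain.
#' @param motion_sd Standard deviation of the shared 0.1--1 Hz band-limited
#'   motion term (multiplicative, dimensionless).
#' @param bleach List with `w_slow`, `tau_slow_s`, `tau_fast_s` describing
#'   the shared double-exponential bleaching
#'   `B(t) = w_slow * exp(-t/tau_slow_s) + (1 - w_slow) * exp(-t/tau_fast_s)`.
#' @param gain_signal,gain_control Channel gains (arbitrary fluorescence
#'   units).
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth(dip_amplitude = -0.05)
#' @export
ground_truth <- function(a_max = 0.05,
                         learning_rate_sessions = 3,
                         nonlaser_amplitude = 0.005,
                         stim_amplitude = 0.10,
                         dip_amplitude = -0.03,
                         dip_tau_rise_s = 0.3,
                         dip_tau_decay_s = 1.0,
                         tonic = 0.10,
                         condition_scale = 1,
                         noise_sd = 0.003,
                         motion_sd = 0.01,
                         bleach = list(w_slow = 0.8, tau_slow_s = 3000,
                                       tau_fast_s = 300),
                         gain_signal = 1.0,
                         gain_control = 0.8) {
  gt <- list(a_max = a_max,
             learning_rate_sessions = learning_rate_sessions,
             nonlaser_amplitude = nonlaser_amplitude,
             stim_amplitude = stim_amplitude,
             dip_amplitude = dip_amplitude,
             dip_tau_rise_s = dip_tau_rise_s,
             dip_tau_decay_s = dip_tau_decay_s,
             tonic = tonic,
             condition_scale = condition_scale,
             noise_sd = noise_sd,
             motion_sd = motion_sd,
             bleach = bleach,
             gain_signal = gain_signal,
             gain_control = gain_control)
  class(gt) <- "ground_truth"
  validate_ground_truth(gt)
  gt
}

validate_ground_truth <- function(gt) {
  for (f in c("a_max", "learning_rate_sessions", "nonlaser_amplitude",
              "stim_amplitude", "dip_amplitude", "tonic", "condition_scale",
              "noise_sd", "motion_sd", "gain_signal", "gain_control"))
    if (!is_scalar_num(gt[[f]])) stopf("ground_truth: `%s` must be a finite number", f)
  if (gt$dip_amplitude > 0)
    stopf("ground_truth: `dip_amplitude` must be <= 0 (it is a dip)")
  if (gt$condition_scale < 0 || gt$condition_scale > 1)
    stopf("ground_truth: `condition_scale` must lie in [0, 1]")
  if (gt$tonic < 0) stopf("ground_truth: `tonic` must be >= 0")
  if (gt$noise_sd < 0 || gt$motion_sd < 0)
    stopf("ground_truth: noise levels must be >= 0")
  if (gt$gain_signal <= 0 || gt$gain_control <= 0)
    stopf("ground_truth: channel gains must be > 0")
  if (gt$learning_rate_sessions <= 0)
    stopf("ground_truth: `learning_rate_sessions` must be > 0")
  check_taus(gt$dip_tau_rise_s, gt$dip_tau_decay_s)
  b <- gt$bleach
  if (!is.list(b) || !all(c("w_slow", "tau_slow_s", "tau_fast_s") %in% names(b)))
    stopf("ground_truth: `bleach` must list w_slow, tau_slow_s, tau_fast_s")
  if (b$w_slow < 0 || b$w_slow > 1 || b$tau_slow_s <= 0 || b$tau_fast_s <= 0)
    stopf("ground_truth: invalid bleaching parameters")
  invisible(gt)
}

#' Learned cue-response amplitude
#'
#' Saturating-exponential acquisition model for cue responses across
#' sessions: laser-paired (and omission, which shares the laser-paired cue)
#' trials follow `A(s) = a_max * (1 - exp(-s / learning_rate_sessions))`;
#' the non-laser cue elicits a constant small response. The curve is
#' non-decreasing in the session index and the laser-paired amplitude never
#' falls below the non-laser amplitude under the defaults.
#'
#' @param session_index 1-based session number (vectorized).
#' @param cue_type `"laser_paired"`, `"omission"` or `"non_laser"`.
#' @param truth A [ground_truth()].
#' @return Amplitude(s) in dF/F units (condition scale not applied).
#' @examples
#' learning_amplitude(1, "laser_paired", ground_truth(a_max = 1,
#'   learning_rate_sessions = 3))  # 1 - exp(-1/3)
#' @export
learning_amplitude <- function(session_index, cue_type, truth = ground_truth()) {
  if (any(session_index < 1)) stopf("`session_index` must be >= 1")
  cue_type <- match.arg(cue_type, TRIAL_TYPES)
  if (cue_type == "non_laser") {
    rep(truth$nonlaser_amplitude, length(session_index))
  } else {
    truth$a_max * (1 - exp(-session_index / truth$learning_rate_sessions))
  }
}

#' Default condition scale factors
#'
#' Multiplicative attenuation applied to response amplitudes per
#' pharmacological/behavioral condition. The D2 antagonist (raclopride)
#' strongly attenuates the orexin response, the D1 antagonist (SCH 23390)
#' leaves it essentially unchanged, and anesthesia does not abolish it.
#'
#' @return Named numeric vector of scale factors in `[0, 1]`.
#' @export
default_condition_scales <- function() {
  c(no_injection = 1.0, vehicle = 1.0, SCH23390 = 0.95, raclopride = 0.35,
    freely_moving = 1.0, anesthetized = 0.85)
}
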