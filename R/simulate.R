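#' Two-channel raw photometry trace
#'
#' Container for a uniformly sampled demodulated recording: time grid `t`,
#' isosbestic control channel `f_control` (405 nm) and signal channel
#' `f_signal` (470 nm), both in arbitrary fluorescence units, plus the
#' sampling rate `fs`. Fluorescence must be strictly positive so division by
#' a fitted baseline is safe.
#'
#' @param t Time grid, seconds (uniform).
#' @param f_control,f_signal Channel samples, same length as `t`.
#' @param fs Sampling rate, Hz.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(t, f_control, f_signal, fs) {
  if (length(t) != length(f_control) || length(t) != length(f_signal))
    stopf("raw_trace: channels and time grid must have equal length")
  if (!is_scalar_num(fs) || fs <= 0) stopf("raw_trace: `fs` must be > 0")
  if (length(t) && (min(f_control) <= 0 || min(f_signal) <= 0))
    stopf("raw_trace: fluorescence must be strictly positive")
  structure(list(t = t, f_control = f_control, f_signal = f_signal, fs = fs),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace: %d samples at %g Hz (%.1f s)\n",
              length(x$t), x$fs, if (length(x$t)) max(x$t) else 0))
  invisible(x)
}

#' @export
plot.raw_trace <- function(x, ...) {
  plot(x$t, x$f_signal, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = "fluorescence (a.u.)",
       ylim = range(c(x$f_signal, x$f_control)), ...)
  lines(x$t, x$f_control, col = "purple")
  legend("topright", c("470 nm signal", "405 nm control"),
         col = c("darkgreen", "purple"), lty = 1, bty = "n")
  invisible(x)
}

# Band-limited (0.1-1 Hz) unit-sd motion noise shared by both channels.
motion_noise <- function(n, fs, sd_target) {
  if (sd_target <= 0 || n < 10) return(numeric(n))
  w <- rnorm(n)
  band <- c(0.1, 1) / (fs / 2)
  band[2] <- min(band[2], 0.99)
  bf <- signal::butter(2, band, type = "pass")
  m <- signal::filtfilt(bf, w)
  s <- sd(m)
  if (s == 0) return(numeric(n))
  m / s * sd_target
}

#' Simulate a two-channel photometry recording from a schedule
#'
#' Forward model of a demodulated fiber-photometry session. The latent
#' sensor signal is
#' `s(t) = tonic + sum_e A_e * k(t - t_e)` with the transient kernel
#' [transient_kernel()]; the channels are
#' `f_signal = gain_signal * B(t) * (1 + m(t)) * (1 + s(t)) + noise` and
#' `f_control = gain_control * B(t) * (1 + m(t)) + noise`, where `B` is
#' shared double-exponential bleaching and `m` shared band-limited motion
#' noise. Laser-paired trials place a response at laser onset (amplitude
#' `stim_amplitude`) and a learned response at cue onset
#' ([learning_amplitude()]); non-laser trials place the small constant cue
#' response; omission trials place the learned cue response plus a
#' negative-amplitude dip kernel at the expected laser onset. All amplitudes
#' are multiplied by `truth$condition_scale` and recorded in the returned
#' manifest.
#'
#' @param schedule An [generate_schedule()] result (or compatible data
#'   frame).
#' @param kernel A [kernel_params()]/[region_kernel()] object.
#' @param truth A [ground_truth()].
#' @param fs Sampling rate, Hz (>= 20 so the fastest preset kernel is
#'   resolved).
#' @param seed Integer seed; traces are deterministic given the seed.
#' @param session_index Session number used for the learning curve; defaults
#'   to the schedule's own.
#' @param pad_s Recording padding (before first event is implicit in the
#'   first ITI; `pad_s` is appended after the last trial), seconds.
#' @param expected_laser_delay_s Laser delay used to place omission dips
#'   when the schedule carries no config attribute.
#' @return A list of class `photometry_sim` with elements `trace`
#'   ([raw_trace()]) and `manifest` (event table with true amplitudes plus
#'   all generative parameters).
#' @examples
#' sim <- simulate_traces(generate_schedule(task_config(), seed = 1),
#'                        region_kernel("LH_dopamine"), ground_truth(),
#'                        fs = 25, seed = 1)
#' sim$trace
#' head(sim$manifest$events)
#' @export
simulate_traces <- function(schedule, kernel, truth = ground_truth(), fs = 25,
                            seed = 1L, session_index = NULL, pad_s = 40,
                            expected_laser_delay_s = NULL) {
  validate_ground_truth(truth)
  if (!inherits(kernel, "kernel_params")) stopf("`kernel` must be kernel_params")
  if (!is_scalar_num(fs) || fs < 20)
    stopf("`fs` must be >= 20 Hz so the fastest kernel is resolved")
  if (is.null(session_index)) {
    session_index <- attr(schedule, "session_index")
    if (is.null(session_index) || is.na(session_index)) session_index <- 1L
  }
  cfg <- attr(schedule, "config")
  if (is.null(expected_laser_delay_s))
    expected_laser_delay_s <- if (!is.null(cfg)) cfg$laser_delay_s else 2

  events <- build_event_table(schedule, truth, session_index,
                              expected_laser_delay_s, kernel)

  t_end <- pad_s + if (nrow(schedule)) max(schedule$cue_offset_s) else 60
  n <- floor(t_end * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  s <- rep(truth$tonic, n)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      te <- events$t_s[i]
      tr_r <- events$tau_rise_s[i]
      tr_d <- events$tau_decay_s[i]
      i0 <- max(1L, floor(te * fs) + 1L)
      i1 <- min(n, ceiling((te + tr_r + 15 * tr_d) * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      s[idx] <- s[idx] + events$amplitude[i] *
        transient_kernel(t[idx] - te, tr_r, tr_d)
    }
  }
  if (min(1 + s) <= 0)
    stopf("simulated fluorescence non-positive at t = %.2f s: dip deeper than tonic + baseline (min 1 + s(t) = %.3f)",
          t[which.min(s)], min(1 + s))

  b <- truth$bleach
  B <- b$w_slow * exp(-t / b$tau_slow_s) + (1 - b$w_slow) * exp(-t / b$tau_fast_s)

  trace <- with_seed(seed, {
    m <- motion_noise(n, fs, truth$motion_sd)
    shared <- B * (1 + m)
    f_sig <- truth$gain_signal * shared * (1 + s) +
      rnorm(n, 0, truth$noise_sd * truth$gain_signal)
    f_ctl <- truth$gain_control * shared +
      rnorm(n, 0, truth$noise_sd * truth$gain_control)
    raw_trace(t, f_ctl, f_sig, fs)
  })

  manifest <- list(events = events, truth = truth, kernel = kernel,
                   fs = fs, seed = seed, session_index = session_index,
                   latent_signal = NULL)
  structure(list(trace = trace, manifest = manifest), class = "photometry_sim")
}

# Per-event table of (trial, event kind, time, true amplitude, kinetics).
# Cue and dip events are phasic (taus scaled by kernel$cue_tau_scale);
# stimulation responses use the full region time constants.
build_event_table <- function(schedule, truth, session_index,
                              expected_laser_delay_s, kernel) {
  empty <- data.frame(trial_index = integer(0), trial_type = character(0),
                      event = character(0), t_s = numeric(0),
                      amplitude = numeric(0), tau_rise_s = numeric(0),
                      tau_decay_s = numeric(0))
  if (!nrow(schedule)) return(empty)
  sc <- truth$condition_scale
  df <- as.data.frame(schedule)
  cue_amp <- ifelse(df$type == "non_laser",
                    learning_amplitude(session_index, "non_laser", truth),
                    learning_amplitude(session_index, "laser_paired", truth)) * sc
  cue <- data.frame(trial_index = df$trial_index, trial_type = df$type,
                    event = "cue", t_s = df$cue_onset_s, amplitude = cue_amp,
                    tau_rise_s = kernel$cue_tau_rise_s,
                    tau_decay_s = kernel$cue_tau_decay_s)
  las <- df[df$type == "laser_paired", , drop = FALSE]
  stim <- data.frame(trial_index = las$trial_index, trial_type = las$type,
                     event = rep("stim", nrow(las)), t_s = las$laser_onset_s,
                     amplitude = rep(truth$stim_amplitude * sc, nrow(las)),
                     tau_rise_s = rep(kernel$tau_rise_s, nrow(las)),
                     tau_decay_s = rep(kernel$tau_decay_s, nrow(las)))
  om <- df[df$type == "omission", , drop = FALSE]
  dip <- data.frame(trial_index = om$trial_index, trial_type = om$type,
                    event = rep("dip", nrow(om)),
                    t_s = om$cue_onset_s + expected_laser_delay_s,
                    amplitude = rep(truth$dip_amplitude * sc, nrow(om)),
                    tau_rise_s = rep(truth$dip_tau_rise_s, nrow(om)),
                    tau_decay_s = rep(truth$dip_tau_decay_s, nrow(om)))
  out <- rbind(cue, stim, dip)
  out <- out[order(out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  out[out$amplitude != 0 | out$event == "cue", , drop = FALSE]
}

#' @export
print.photometry_sim <- function(x, ...) {
  cat(sprintf("photometry_sim [%s], session %d, seed %d\n",
              x$manifest$kernel$region_label, x$manifest$session_index,
              x$manifest$seed))
  print(x$trace)
  cat(sprintf("  %d ground-truth events\n", nrow(x$manifest$events)))
  invisible(x)
}

#' Write / read a raw trace as CSV
#'
#' Three data columns `t_s,f405,f470`; the sampling rate is stored in a
#' `# fs_hz=` comment header line.
#'
#' @param trace A [raw_trace()].
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [raw_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", trace$fs), con)
  write.csv(data.frame(t_s = trace$t, f405 = trace$f_control,
                       f470 = trace$f_signal),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# fs_hz=", hdr)) stopf("trace CSV missing '# fs_hz=' header")
  fs <- as.numeric(sub("^# fs_hz=", "", hdr))
  df <- read.csv(path, comment.char = "#")
  if (!identical(names(df), c("t_s", "f405", "f470")))
    stopf("trace CSV must have columns t_s,f405,f470")
  raw_trace(df$t_s, df$f405, df$f470, fs)
}
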