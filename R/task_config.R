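#' Opto-Pavlovian session design parameters
#'
#' Bundles every timing and count parameter of an opto-Pavlovian session.
#' Defaults follow the standard design: a 7 s compound cue; on laser-paired
#' trials the laser starts 2 s after cue onset and lasts 5 s (20 Hz, 10 ms
#' pulses); 30 laser-paired and 30 non-laser cues per training session with
#' uniform 45--75 s inter-trial intervals; in omission mode one third of the
#' laser-paired cues (10 of 30) are presented without the laser.
#'
#' @param cue_duration_s Cue duration in seconds.
#' @param laser_delay_s Laser onset relative to cue onset, seconds.
#' @param laser_duration_s Laser train duration, seconds.
#' @param pulse_rate_hz Laser pulse rate, Hz.
#' @param pulse_width_s Single pulse width, seconds.
#' @param iti_low_s,iti_high_s Bounds of the uniform inter-trial interval
#'   (cue offset to next cue onset), seconds.
#' @param n_laser_trials Number of laser-paired cue presentations. In
#'   omission mode this is the total count of laser-paired cues, of which
#'   `n_omission_trials` are presented without the laser.
#' @param n_nonlaser_trials Number of non-laser cue presentations.
#' @param omission_mode If `TRUE`, `n_omission_trials` of the laser-paired
#'   cues omit the laser.
#' @param n_omission_trials Number of omission trials (omission mode only).
#' @param max_run_length Maximum number of consecutive trials of the same
#'   type allowed by the pseudorandom sequence.
#' @param n_pulses_terminal Pulses per train in terminal-stimulation mode
#'   (see [generate_pulse_train()]).
#'
#' @return An object of class `task_config`.
#' @examples
#' task_config()
#' task_config(omission_mode = TRUE)
#' @export
task_config <- function(cue_duration_s = 7,
                        laser_delay_s = 2,
                        laser_duration_s = 5,
                        pulse_rate_hz = 20,
                        pulse_width_s = 0.010,
                        iti_low_s = 45,
                        iti_high_s = 75,
                        n_laser_trials = 30,
                        n_nonlaser_trials = 30,
                        omission_mode = FALSE,
                        n_omission_trials = if (omission_mode) 10 else 0,
                        max_run_length = 3,
                        n_pulses_terminal = 100) {
  cfg <- list(
    cue_duration_s = cue_duration_s,
    laser_delay_s = laser_delay_s,
    laser_duration_s = laser_duration_s,
    pulse_rate_hz = pulse_rate_hz,
    pulse_width_s = pulse_width_s,
    iti_low_s = iti_low_s,
    iti_high_s = iti_high_s,
    n_laser_trials = as.integer(n_laser_trials),
    n_nonlaser_trials = as.integer(n_nonlaser_trials),
    omission_mode = isTRUE(omission_mode),
    n_omission_trials = as.integer(n_omission_trials),
    max_run_length = as.integer(max_run_length),
    n_pulses_terminal = as.integer(n_pulses_terminal)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  num <- c("cue_duration_s", "laser_delay_s", "laser_duration_s",
           "pulse_rate_hz", "pulse_width_s", "iti_low_s", "iti_high_s")
  for (f in num)
    if (!is_scalar_num(cfg[[f]])) stopf("task_config: `%s` must be a finite number", f)
  pos <- c("cue_duration_s", "laser_duration_s", "pulse_rate_hz",
           "pulse_width_s", "iti_low_s", "iti_high_s")
  for (f in pos)
    if (cfg[[f]] <= 0) stopf("task_config: `%s` must be > 0", f)
  if (cfg$laser_delay_s < 0) stopf("task_config: `laser_delay_s` must be >= 0")
  if (cfg$iti_low_s > cfg$iti_high_s)
    stopf("task_config: iti_low_s (%g) > iti_high_s (%g)", cfg$iti_low_s, cfg$iti_high_s)
  if (cfg$laser_delay_s + cfg$laser_duration_s > cfg$cue_duration_s)
    stopf("task_config: laser_delay_s + laser_duration_s (%g) exceeds cue_duration_s (%g)",
          cfg$laser_delay_s + cfg$laser_duration_s, cfg$cue_duration_s)
  cnt <- c("n_laser_trials", "n_nonlaser_trials", "n_omission_trials",
           "max_run_length", "n_pulses_terminal")
  for (f in cnt)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stopf("task_config: `%s` must be a non-negative count", f)
  if (cfg$max_run_length < 1) stopf("task_config: `max_run_length` must be >= 1")
  if (cfg$omission_mode) {
    if (cfg$n_omission_trials >= cfg$n_laser_trials && cfg$n_laser_trials > 0)
      stopf("task_config: n_omission_trials (%d) must be < n_laser_trials (%d)",
            cfg$n_omission_trials, cfg$n_laser_trials)
  } else if (cfg$n_omission_trials != 0) {
    stopf("task_config: n_omission_trials must be 0 unless omission_mode is TRUE")
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Opto-Pavlovian task configuration\n")
  cat(sprintf("  cue: %g s; laser: +%g s for %g s (%g Hz, %g ms pulses)\n",
              x$cue_duration_s, x$laser_delay_s, x$laser_duration_s,
              x$pulse_rate_hz, 1000 * x$pulse_width_s))
  cat(sprintf("  ITI: uniform [%g, %g] s; max run length %d\n",
              x$iti_low_s, x$iti_high_s, x$max_run_length))
  if (x$omission_mode)
    cat(sprintf("  trials: %d laser + %d omission + %d non-laser (omission mode)\n",
                x$n_laser_trials - x$n_omission_trials, x$n_omission_trials,
                x$n_nonlaser_trials))
  else
    cat(sprintf("  trials: %d laser-paired + %d non-laser\n",
                x$n_laser_trials, x$n_nonlaser_trials))
  invisible(x)
}
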