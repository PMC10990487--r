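TRIAL_TYPES <- c("laser_paired", "non_laser", "omission")

#' Generate a pseudorandom opto-Pavlovian trial schedule
#'
#' Allocates the exact configured number of trials of each type, shuffles the
#' sequence under the constraint that no trial type occurs more than
#' `max_run_length` times in a row (rejection resampling with a retry cap),
#' and assigns absolute event times with inter-trial intervals (cue offset to
#' next cue onset) drawn uniformly on `[iti_low_s, iti_high_s]`. Event times
#' are rounded to 1 ms so schedules survive a CSV round trip exactly.
#'
#' In omission mode `n_omission_trials` of the `n_laser_trials` laser-paired
#' cues are typed `omission` and carry no laser times; with the defaults this
#' yields 20 laser, 10 omission and 30 non-laser trials per session.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param session_index 1-based session number stored with the schedule.
#' @param max_tries Retry cap for the run-length rejection sampler.
#'
#' @return An `event_schedule`: a data frame with columns `trial_index`,
#'   `type`, `cue_onset_s`, `cue_offset_s`, `laser_onset_s`, `laser_offset_s`
#'   (`NA` where the laser is absent), with the config, seed and
#'   `session_index` stored as attributes.
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' table(sched$type)
#' @export
generate_schedule <- function(config, seed, session_index = 1L,
                              max_tries = 1000L) {
  validate_task_config(config)
  n_laser <- config$n_laser_trials - config$n_omission_trials
  counts <- c(laser_paired = n_laser,
              omission = config$n_omission_trials,
              non_laser = config$n_nonlaser_trials)
  counts <- counts[counts > 0]
  n <- sum(counts)

  if (n > 0) {
    # A sequence with max run L exists iff the most frequent type fits into
    # the L-slots created by the remaining trials.
    L <- config$max_run_length
    if (max(counts) > L * (n - max(counts) + 1))
      stopf("run-length constraint infeasible: %d trials of one type cannot be arranged with max run %d among %d trials",
            max(counts), L, n)
  }

  types <- character(0)
  itis <- numeric(0)
  if (n > 0) {
    drawn <- with_seed(seed, {
      pool <- rep(names(counts), times = counts)
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        cand <- sample(pool)
        if (max_run_length(cand) <= config$max_run_length) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stopf("failed to satisfy run-length constraint in %d shuffles", max_tries)
      list(types = cand,
           itis = round(runif(n, config$iti_low_s, config$iti_high_s), 3))
    })
    types <- drawn$types
    itis <- drawn$itis
  }

  cue_onset <- numeric(n)
  prev_end <- 0
  for (i in seq_len(n)) {
    cue_onset[i] <- round(prev_end + itis[i], 3)
    prev_end <- cue_onset[i] + config$cue_duration_s
  }
  cue_offset <- cue_onset + config$cue_duration_s
  has_laser <- types == "laser_paired"
  laser_onset <- ifelse(has_laser, cue_onset + config$laser_delay_s, NA_real_)
  laser_offset <- ifelse(has_laser, laser_onset + config$laser_duration_s, NA_real_)

  sched <- data.frame(
    trial_index = seq_len(n),
    type = types,
    cue_onset_s = cue_onset,
    cue_offset_s = cue_offset,
    laser_onset_s = laser_onset,
    laser_offset_s = laser_offset,
    stringsAsFactors = FALSE
  )
  new_event_schedule(sched, config = config, seed = seed,
                     session_index = session_index)
}

new_event_schedule <- function(df, config = NULL, seed = NA_integer_,
                               session_index = NA_integer_) {
  attr(df, "config") <- config
  attr(df, "seed") <- seed
  attr(df, "session_index") <- as.integer(session_index)
  class(df) <- c("event_schedule", "data.frame")
  df
}

max_run_length <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(x)$lengths)
}

#' Inter-trial intervals of a schedule
#'
#' Intervals from each cue offset to the next cue onset, including the
#' interval preceding the first trial (from recording start).
#'
#' @param schedule An `event_schedule`.
#' @return Numeric vector of intervals in seconds (length = number of trials).
#' @export
schedule_itis <- function(schedule) {
  n <- nrow(schedule)
  if (n == 0) return(numeric(0))
  schedule$cue_onset_s - c(0, schedule$cue_offset_s[-n])
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Opto-Pavlovian event schedule: %d trials (session %s, seed %s)\n",
              nrow(x), attr(x, "session_index"), attr(x, "seed")))
  if (nrow(x) > 0) {
    tab <- table(x$type)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
    print(head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat(sprintf("  ... %d more trials\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Generate an optogenetic pulse train
#'
#' Regular pulse onsets spaced exactly `1/rate_hz` apart, as used for
#' terminal stimulation (20 Hz, 100 pulses of 10 ms).
#'
#' @param rate_hz Pulse rate in Hz.
#' @param n_pulses Number of pulses.
#' @param width_s Pulse width in seconds; the duty cycle `rate_hz * width_s`
#'   must be < 1.
#' @param t0 Onset time of the first pulse, seconds.
#' @return Data frame with columns `onset_s`, `offset_s`, one row per pulse.
#' @examples
#' train <- generate_pulse_train(20, 100, 0.01)
#' diff(train$onset_s)[1]  # 0.05 s
#' @export
generate_pulse_train <- function(rate_hz, n_pulses, width_s = 0.010, t0 = 0) {
  if (!is_scalar_num(rate_hz) || rate_hz <= 0) stopf("`rate_hz` must be > 0")
  if (!is_scalar_num(width_s) || width_s <= 0) stopf("`width_s` must be > 0")
  if (n_pulses < 1) stopf("`n_pulses` must be >= 1")
  if (rate_hz * width_s >= 1)
    stopf("duty cycle rate_hz * width_s = %g >= 1; pulses overlap", rate_hz * width_s)
  onset <- t0 + (seq_len(n_pulses) - 1) / rate_hz
  data.frame(onset_s = onset, offset_s = onset + width_s)
}

#' Write / read an event schedule as CSV
#'
#' The CSV has columns `trial_index,type,cue_onset_s,cue_offset_s,
#' laser_onset_s,laser_offset_s`; laser fields are empty for trials without
#' laser. Times are written at millisecond precision, matching the 1 ms
#' resolution of generated schedules, so a write/read round trip is lossless.
#'
#' @param schedule An `event_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a validated `event_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  out <- data.frame(
    trial_index = df$trial_index,
    type = df$type,
    cue_onset_s = fmt(df$cue_onset_s),
    cue_offset_s = fmt(df$cue_offset_s),
    laser_onset_s = fmt(df$laser_onset_s),
    laser_offset_s = fmt(df$laser_offset_s),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  cols <- c("trial_index", "type", "cue_onset_s", "cue_offset_s",
            "laser_onset_s", "laser_offset_s")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(trial_index = "integer", type = "character",
                                cue_onset_s = "numeric", cue_offset_s = "numeric",
                                laser_onset_s = "numeric", laser_offset_s = "numeric"))
  if (!identical(names(df), cols))
    stopf("schedule CSV must have columns %s", paste(cols, collapse = ","))
  validate_schedule_rows(df)
  new_event_schedule(df)
}

# Row-level validation; error messages cite CSV line numbers (header = line 1).
validate_schedule_rows <- function(df) {
  line <- function(i) i + 1L
  bad_type <- which(!df$type %in% TRIAL_TYPES)
  if (length(bad_type))
    stopf("invalid trial type at line(s) %s", paste(line(bad_type), collapse = ", "))
  bad_time <- which(!is.finite(df$cue_onset_s) | !is.finite(df$cue_offset_s) |
                      df$cue_offset_s <= df$cue_onset_s)
  if (length(bad_time))
    stopf("malformed cue times at line(s) %s", paste(line(bad_time), collapse = ", "))
  need_laser <- df$type == "laser_paired"
  bad_laser <- which(need_laser & (!is.finite(df$laser_onset_s) |
                                     !is.finite(df$laser_offset_s)))
  if (length(bad_laser))
    stopf("missing laser times on laser_paired trial at line(s) %s",
          paste(line(bad_laser), collapse = ", "))
  stray <- which(!need_laser & (is.finite(df$laser_onset_s) |
                                  is.finite(df$laser_offset_s)))
  if (length(stray))
    stopf("laser times present on %s trial at line(s) %s",
          df$type[stray[1]], paste(line(stray), collapse = ", "))
  if (nrow(df) > 1) {
    overlap <- which(df$cue_onset_s[-1] <= df$cue_offset_s[-nrow(df)])
    if (length(overlap))
      stopf("overlapping/non-increasing trials at line(s) %s",
            paste(line(overlap + 1L), collapse = ", "))
  }
  invisible(df)
}
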