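# Shared fixtures, built in code at test time.

# Compact task for unit tests where session length is irrelevant.
quick_task <- function(n_laser = 4, n_nonlaser = 4, omission = FALSE,
                       n_omission = if (omission) 2 else 0) {
  task_config(iti_low_s = 8, iti_high_s = 12, n_laser_trials = n_laser,
              n_nonlaser_trials = n_nonlaser, omission_mode = omission,
              n_omission_trials = n_omission)
}

# No noise, no motion, and exactly flat bleaching (B identically 1).
noiseless_truth <- function(...) {
  ground_truth(noise_sd = 0, motion_sd = 0,
               bleach = list(w_slow = 1, tau_slow_s = Inf, tau_fast_s = 1), ...)
}

# dff_trace built directly from samples (bypasses the isosbestic stage).
make_dff <- function(dff, fs, t0 = 0) {
  dff_trace(t0 + (seq_along(dff) - 1) / fs, dff, fs)
}

# Single-trial schedule with a laser event; convenient for kernel tests.
single_trial_schedule <- function(cue_onset = 20, omission = FALSE) {
  type <- if (omission) "omission" else "laser_paired"
  df <- data.frame(trial_index = 1L, type = type,
                   cue_onset_s = cue_onset, cue_offset_s = cue_onset + 7,
                   laser_onset_s = if (omission) NA_real_ else cue_onset + 2,
                   laser_offset_s = if (omission) NA_real_ else cue_onset + 7)
  optopav:::new_event_schedule(df, config = task_config(), seed = 0L,
                               session_index = 1L)
}
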