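test_that("alignment baselines each trial and keeps one row per trial", {
  sch <- generate_schedule(task_config(iti_low_s = 8, iti_high_s = 12),
                           seed = 1)
  fs <- 25
  n <- ceiling((max(sch$cue_offset_s) + 30) * fs)
  const <- make_dff(rep(0.42, n), fs)
  tens <- align_trials(const, sch, "cue_onset", window_s = c(-2, 3),
                       baseline_window_s = c(-2, 0))
  expect_equal(nrow(tens$data), 60)
  expect_equal(max(abs(tens$data)), 0, tolerance = 1e-12)

  las <- align_trials(const, sch, "laser_onset", window_s = c(-2, 3),
                      baseline_window_s = c(-2, 0))
  expect_equal(nrow(las$data), 30)
})

test_that("synthetic laser trials peak at the stimulation-kernel latency", {
  # noise-free but with realistic bleaching so the isosbestic fit is defined
  gt <- ground_truth(noise_sd = 0, motion_sd = 0, a_max = 0,
                     nonlaser_amplitude = 0, tonic = 0.1)
  kern <- region_kernel("LH_dopamine")
  sch <- single_trial_schedule(cue_onset = 30)
  fs <- 100
  sim <- simulate_traces(sch, kern, gt, fs = fs, seed = 1)
  dff <- compute_dff(sim$trace)
  tens <- align_trials(dff, sch, "laser_onset", window_s = c(-2, 10),
                       baseline_window_s = c(-2, 0))
  peak_rel <- tens$rel_t[which.max(tens$data[1, ])]
  expect_equal(peak_rel, kernel_peak_time(kern$tau_rise_s, kern$tau_decay_s),
               tolerance = 1.5 / fs)
})

test_that("out-of-recording events are dropped with a warning, all-dropped fails", {
  sch <- generate_schedule(quick_task(2, 2), seed = 2)
  fs <- 25
  short_n <- ceiling((sch$cue_onset_s[nrow(sch)] - 1) * fs)
  dff <- make_dff(rnorm(short_n, 0, 1e-3), fs)
  expect_warning(
    tens <- align_trials(dff, sch, "cue_onset", window_s = c(-2, 3),
                         baseline_window_s = c(-2, 0)),
    "dropping")
  expect_lt(nrow(tens$data), 4)

  tiny <- make_dff(rnorm(10), fs)
  expect_error(
    suppressWarnings(align_trials(tiny, sch, "cue_onset",
                                  window_s = c(-2, 3),
                                  baseline_window_s = c(-2, 0))),
    "all trials dropped")
})

test_that("AUC integrates rows trapezoidally over the requested window", {
  fs <- 100
  rel_t <- seq(-2, 4, by = 1 / fs)
  tensor <- structure(list(
    data = rbind(rep(0.5, length(rel_t)), rep(0, length(rel_t))),
    rel_t = rel_t, event_label = "cue_onset", baseline_window_s = c(-2, 0),
    trial_index = 1:2, trial_type = c("laser_paired", "laser_paired"),
    fs = fs), class = "perievent_tensor")
  auc <- trial_auc(tensor, c(0, 1.5))
  expect_equal(auc, c(0.75, 0))
  expect_error(trial_auc(tensor, c(4.2, 4.5)), "empty AUC window")
})

test_that("noiseless kernel AUC matches the closed-form integral", {
  fs <- 1000
  rel_t <- seq(0, 5, by = 1 / fs)
  taus <- c(0.3, 1.2)
  row <- transient_kernel(rel_t, taus[1], taus[2])
  tensor <- structure(list(data = matrix(row, nrow = 1), rel_t = rel_t,
                           event_label = "laser_onset",
                           baseline_window_s = c(-1, 0), trial_index = 1L,
                           trial_type = "laser_paired", fs = fs),
                      class = "perievent_tensor")
  expect_equal(trial_auc(tensor, c(0, 1.5)),
               kernel_window_integral(taus[1], taus[2], 0, 1.5),
               tolerance = 1e-4)
})

test_that("AUC is linear and invariant to constant offsets", {
  fs <- 50
  rel_t <- seq(-1, 2, by = 1 / fs)
  set.seed(8)
  x <- rnorm(length(rel_t))
  y <- rnorm(length(rel_t))
  mk <- function(rows) structure(list(data = rows, rel_t = rel_t,
                                      event_label = "cue_onset",
                                      baseline_window_s = c(-1, 0),
                                      trial_index = seq_len(nrow(rows)),
                                      trial_type = rep("laser_paired", nrow(rows)),
                                      fs = fs), class = "perievent_tensor")
  w <- c(0, 1.5)
  expect_equal(trial_auc(mk(rbind(2 * x + 3 * y)), w),
               2 * trial_auc(mk(rbind(x)), w) + 3 * trial_auc(mk(rbind(y)), w),
               tolerance = 1e-10)

  # adding a constant before baselining leaves the baselined AUC unchanged
  sch <- generate_schedule(quick_task(3, 1), seed = 9)
  n <- ceiling((max(sch$cue_offset_s) + 30) * fs)
  set.seed(10)
  base_sig <- rnorm(n, 0, 0.01)
  t1 <- align_trials(make_dff(base_sig, fs), sch, "cue_onset",
                     window_s = c(-1, 2), baseline_window_s = c(-1, 0))
  t2 <- align_trials(make_dff(base_sig + 0.37, fs), sch, "cue_onset",
                     window_s = c(-1, 2), baseline_window_s = c(-1, 0))
  expect_equal(trial_auc(t1, w), trial_auc(t2, w), tolerance = 1e-10)
})

test_that("omission AUC uses exactly the omission trials and catches dips", {
  sch <- generate_schedule(task_config(omission_mode = TRUE), seed = 3,
                           session_index = 11)
  gt <- ground_truth(noise_sd = 0, motion_sd = 0)
  sim <- simulate_traces(sch, region_kernel("NAc_dopamine"), gt, fs = 25,
                         seed = 4, session_index = 11)
  dff <- compute_dff(sim$trace)
  tens <- align_trials(dff, sch, "omission_expected_laser",
                       window_s = c(-4, 3), baseline_window_s = c(-4, -2))
  expect_equal(nrow(tens$data), 10)
  expect_lt(omission_auc(tens, c(0, 2)), 0)

  # zero rows give zero AUC
  zero <- tens
  zero$data[] <- 0
  expect_equal(omission_auc(zero, c(0, 2)), 0)

  # mixed-type tensors are rejected
  cue_tens <- align_trials(dff, sch, "cue_onset", window_s = c(-2, 3),
                           baseline_window_s = c(-2, 0))
  expect_error(omission_auc(cue_tens), "omission trials only")
})

test_that("session curves aggregate to one mean per cell and flag missing cells", {
  tab <- expand.grid(subject = 1:4, session = 1:10,
                     type = c("laser_paired", "non_laser"),
                     stringsAsFactors = FALSE)
  tab <- rbind(tab, tab)   # two trials per cell
  tab$auc <- 1
  curve <- session_curve(tab)
  expect_equal(nrow(curve), 80)
  expect_true(all(curve$auc == 1))

  expect_error(session_curve(tab[tab$subject != 2 | tab$session != 5, ]),
               "missing cells")
})

test_that("noiseless learning runs give a strictly increasing laser-cue curve", {
  gt <- noiseless_truth()
  fs <- 250
  # real inter-trial intervals: shortened ITIs would let the slowly decaying
  # stimulation response of the previous trial contaminate the cue window
  task <- task_config(n_laser_trials = 4, n_nonlaser_trials = 4)
  rows <- lapply(1:10, function(ses) {
    sch <- generate_schedule(task, seed = 100 + ses, session_index = ses)
    sim <- simulate_traces(sch, region_kernel("NAc_dopamine"), gt, fs = fs,
                           seed = 200 + ses, session_index = ses)
    # artifact-free latent dF/F (bleaching is flat in noiseless_truth)
    dff <- make_dff(sim$trace$f_signal / gt$gain_signal - 1 - gt$tonic, fs)
    tens <- align_trials(dff, sch, "cue_onset", window_s = c(-2, 2),
                         baseline_window_s = c(-2, 0))
    data.frame(subject = 1, session = ses, type = tens$trial_type,
               auc = trial_auc(tens, c(0, 1.5)))
  })
  curve <- session_curve(do.call(rbind, rows))
  laser <- curve$auc[curve$type == "laser_paired"]
  expect_true(all(diff(laser) > 0))
  expect_true(all(laser >= curve$auc[curve$type == "non_laser"]))
})
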