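# Simulation studies: parameter-recovery and calibration experiments run
# entirely on synthetic cohorts. These are the package's quantitative
# self-checks; the vignette discusses what they do and do not establish.

#' Region-ordering recovery study
#'
#' For each replicate, simulates an omission session for `n_subjects`
#' subjects per region preset (slow accumbens vs fast hypothalamus
#' stimulation kinetics), runs the full analysis path (isosbestic dF/F0,
#' laser-aligned tensors, smoothed-derivative zero crossing of the
#' subject-mean trace) and records whether the mean hypothalamic point A
#' precedes the accumbal one.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param n_subjects Subjects per region.
#' @param seed Master seed.
#' @param fs Sampling rate, Hz.
#' @param truth Generative [ground_truth()] (default noise levels).
#' @param smoothing_window_s Derivative smoothing window, seconds.
#' @return Data frame with one row per replicate: mean point A per region
#'   and the logical `ordered` (LH before NAc).
#' @export
recovery_region_ordering <- function(n_seeds = 100, n_subjects = 4, seed = 1,
                                     fs = 25, truth = ground_truth(),
                                     smoothing_window_s = 0.5) {
  task <- task_config(omission_mode = TRUE)
  point_a <- function(region, sd0) {
    sch <- generate_schedule(task, seed = sd0, session_index = 11L)
    sim <- simulate_traces(sch, region_kernel(region), truth, fs = fs,
                           seed = sd0 + 1L, session_index = 11L)
    tens <- align_trials(compute_dff(sim$trace), sch, "laser_onset",
                         window_s = c(-2, 12), baseline_window_s = c(-2, 0))
    tensor_zero_crossings(tens, 0, smoothing_window_s)$point_a_s
  }
  out <- lapply(seq_len(n_seeds), function(i) {
    nac <- vapply(seq_len(n_subjects), function(s)
      point_a("NAc_dopamine", child_seed(seed, i * 1000 + s)), numeric(1))
    lh <- vapply(seq_len(n_subjects), function(s)
      point_a("LH_dopamine", child_seed(seed, i * 1000 + 500 + s)), numeric(1))
    data.frame(replicate = i, point_a_nac_s = mean(nac),
               point_a_lh_s = mean(lh), ordered = mean(lh) < mean(nac))
  })
  do.call(rbind, out)
}

#' Omission-dip recovery study
#'
#' For each replicate, simulates omission sessions for a cohort with
#' between-subject amplitude variability, measures the per-subject dip AUC
#' (baselined before the cue, integrated over the window after the expected
#' laser onset) and applies the one-sample t test against zero.
#'
#' @inheritParams recovery_region_ordering
#' @param dip_amplitude Ground-truth dip amplitude (use 0 for the null
#'   calibration).
#' @param subject_cv Between-subject amplitude coefficient of variation.
#' @param window_s Dip AUC window, seconds after expected laser onset.
#' @return Data frame per replicate: mean subject AUC, t and p of the
#'   one-sample test, and `negative_significant`.
#' @export
recovery_omission_dip <- function(n_seeds = 100, n_subjects = 4, seed = 1,
                                  dip_amplitude = -0.03, fs = 25,
                                  subject_cv = 0.15, window_s = c(0, 2)) {
  task <- task_config(omission_mode = TRUE)
  base <- ground_truth()
  base$dip_amplitude <- dip_amplitude
  out <- lapply(seq_len(n_seeds), function(i) {
    sfac <- subject_factors(n_subjects, subject_cv,
                            child_seed(seed, 90000 + i))
    auc <- vapply(seq_len(n_subjects), function(s) {
      truth_s <- subject_truth(base, sfac[s])
      sd0 <- child_seed(seed, i * 1000 + s)
      sch <- generate_schedule(task, seed = sd0, session_index = 11L)
      sim <- simulate_traces(sch, region_kernel("NAc_dopamine"), truth_s,
                             fs = fs, seed = sd0 + 1L, session_index = 11L)
      tens <- align_trials(compute_dff(sim$trace), sch,
                           "omission_expected_laser",
                           window_s = c(-4, window_s[2] + 1),
                           baseline_window_s = c(-4, -2))
      omission_auc(tens, window_s)
    }, numeric(1))
    tt <- one_sample_t(auc)
    data.frame(replicate = i, mean_auc = mean(auc), t = tt$statistic,
               p = tt$p_value,
               negative_significant = tt$p_value < 0.05 && mean(auc) < 0)
  })
  do.call(rbind, out)
}

#' Learning-curve recovery study
#'
#' For each replicate, simulates a full 10-session training cohort, builds
#' the per-subject session x cue AUC learning curve and tests the
#' session x cue interaction with the two-way repeated-measures ANOVA.
#'
#' @inheritParams recovery_omission_dip
#' @param n_sessions Training sessions per cohort.
#' @param a_max Asymptotic learned amplitude (0 for a null cohort).
#' @return Data frame per replicate: interaction F, its df pair, p, and
#'   `significant`.
#' @export
recovery_learning_interaction <- function(n_seeds = 100, n_subjects = 4,
                                          n_sessions = 10, seed = 1,
                                          a_max = ground_truth()$a_max,
                                          fs = 25, subject_cv = 0.15) {
  task <- task_config()
  base <- ground_truth()
  base$a_max <- a_max
  out <- lapply(seq_len(n_seeds), function(i) {
    sfac <- subject_factors(n_subjects, subject_cv,
                            child_seed(seed, 80000 + i))
    rows <- list()
    for (subj in seq_len(n_subjects)) {
      truth_s <- subject_truth(base, sfac[subj])
      for (ses in seq_len(n_sessions)) {
        sd0 <- child_seed(seed, i * 2000 + subj * 60 + ses)
        sch <- generate_schedule(task, seed = sd0, session_index = ses)
        sim <- simulate_traces(sch, region_kernel("NAc_dopamine"), truth_s,
                               fs = fs, seed = sd0 + 1L, session_index = ses)
        tens <- align_trials(compute_dff(sim$trace), sch, "cue_onset",
                             window_s = c(-2, 2),
                             baseline_window_s = c(-2, 0))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, session = ses, type = tens$trial_type,
          auc = trial_auc(tens, c(0, 1.5)))
      }
    }
    curve <- session_curve(do.call(rbind, rows))
    res <- two_way_rm_anova(data.frame(subject = curve$subject,
                                       session = curve$session,
                                       cue = curve$type, value = curve$auc))
    data.frame(replicate = i,
               f_interaction = unname(res$statistic["session:cue"]),
               df1 = res$df[["session:cue"]][1],
               df2 = res$df[["session:cue"]][2],
               p = unname(res$p_value["session:cue"]),
               significant = unname(res$p_value["session:cue"]) < 0.05)
  })
  do.call(rbind, out)
}

#' Type-I error calibration of the statistical layer
#'
#' Simulates null data (iid Gaussian, no effects) and records the rejection
#' rate of each implemented test at alpha = 0.05. Under the null every
#' test is exact, so the empirical rate should sit inside the binomial
#' sampling band around 0.05.
#'
#' @param n_reps Null replicates per test.
#' @param seed Master seed.
#' @param alpha Significance threshold.
#' @return Named numeric vector of rejection rates for `one_sample_t`,
#'   `unpaired_t`, `paired_t`, `one_way_rm_anova` and `two_way_rm_anova`
#'   (interaction term).
#' @export
type1_calibration <- function(n_reps = 2000, seed = 1, alpha = 0.05) {
  with_seed(seed, {
    p_one <- replicate(n_reps, one_sample_t(rnorm(8))$p_value)
    p_unp <- replicate(n_reps, unpaired_t(rnorm(8), rnorm(8))$p_value)
    p_pai <- replicate(n_reps, paired_t(rnorm(8), rnorm(8))$p_value)
    tab1 <- expand.grid(subject = 1:4, condition = letters[1:3])
    p_rm1 <- replicate(n_reps, {
      tab1$value <- rnorm(nrow(tab1))
      one_way_rm_anova(tab1, posthoc = FALSE)$p_value
    })
    tab2 <- expand.grid(subject = 1:4, session = 1:3, cue = c("x", "y"))
    p_rm2 <- replicate(n_reps, {
      tab2$value <- rnorm(nrow(tab2))
      unname(two_way_rm_anova(tab2)$p_value["session:cue"])
    })
    c(one_sample_t = mean(p_one < alpha),
      unpaired_t = mean(p_unp < alpha),
      paired_t = mean(p_pai < alpha),
      one_way_rm_anova = mean(p_rm1 < alpha),
      two_way_rm_anova = mean(p_rm2 < alpha))
  })
}
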