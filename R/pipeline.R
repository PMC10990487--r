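#' Configuration of the end-to-end synthetic experiment pipeline
#'
#' Describes a replicate-style experiment: a cohort trained for
#' `n_sessions` opto-Pavlovian sessions (learning curve), an omission
#' session, a two-region kinetics comparison, and a terminal-stimulation
#' condition experiment (locomotion control + receptor antagonists). All
#' analysis windows are in seconds; the time convention is 0-based seconds
#' from recording start with half-open alignment windows `[lo, hi)`.
#'
#' @param n_subjects Cohort size for learning/omission/kinetics components.
#' @param n_sessions Number of training sessions.
#' @param fs Sampling rate for simulated recordings, Hz.
#' @param region Sensor/region preset of the main cohort
#'   (see [region_kernel()]).
#' @param task Training-session [task_config()].
#' @param omission_task Omission-session [task_config()].
#' @param truth Cohort-level [ground_truth()].
#' @param subject_cv Between-subject coefficient of variation of response
#'   amplitudes (multiplicative, truncated at 0.2).
#' @param auc_window_s Cue-response AUC window, seconds from cue onset.
#' @param omission_window_s Dip AUC window, seconds from expected laser
#'   onset.
#' @param baseline_window_s Per-trial baseline window, seconds.
#' @param smoothing_window_s Derivative smoothing window, seconds.
#' @param lowpass_hz Optional zero-phase low-pass cutoff applied to dF/F0
#'   (`NULL` = none; simulated traces are already band-limited).
#' @param kinetics_regions Two region presets compared by the kinetics
#'   component.
#' @param conditions Condition labels of the terminal-stimulation drug
#'   experiment.
#' @param condition_scales Named amplitude scale factors per condition
#'   (see [default_condition_scales()]).
#' @param n_subjects_terminal Cohort size of the terminal-stimulation
#'   experiments.
#' @param n_stim_trials Stimulation trains per terminal session.
#' @param stim_auc_long_s,stim_auc_short_s AUC windows for the locomotion
#'   (0--20 s) and drug (0--5 s) comparisons.
#' @param seed Master seed; every stage seed is derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 4,
                            n_sessions = 10,
                            fs = 25,
                            region = "NAc_dopamine",
                            task = task_config(),
                            omission_task = task_config(omission_mode = TRUE),
                            truth = ground_truth(),
                            subject_cv = 0.15,
                            auc_window_s = c(0, 1.5),
                            omission_window_s = c(0, 2),
                            baseline_window_s = c(-2, 0),
                            smoothing_window_s = 0.5,
                            lowpass_hz = NULL,
                            kinetics_regions = c("NAc_dopamine", "LH_dopamine"),
                            conditions = c("no_injection", "vehicle",
                                           "SCH23390", "raclopride"),
                            condition_scales = default_condition_scales(),
                            n_subjects_terminal = 3,
                            n_stim_trials = 5,
                            stim_auc_long_s = c(0, 20),
                            stim_auc_short_s = c(0, 5),
                            seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions), fs = fs, region = region,
              task = task, omission_task = omission_task, truth = truth,
              subject_cv = subject_cv, auc_window_s = auc_window_s,
              omission_window_s = omission_window_s,
              baseline_window_s = baseline_window_s,
              smoothing_window_s = smoothing_window_s, lowpass_hz = lowpass_hz,
              kinetics_regions = kinetics_regions, conditions = conditions,
              condition_scales = condition_scales,
              n_subjects_terminal = as.integer(n_subjects_terminal),
              n_stim_trials = as.integer(n_stim_trials),
              stim_auc_long_s = stim_auc_long_s,
              stim_auc_short_s = stim_auc_short_s,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n_subjects < 2) stopf("pipeline_config: need >= 2 subjects")
  if (cfg$n_sessions < 1) stopf("pipeline_config: need >= 1 session")
  for (w in c("auc_window_s", "omission_window_s", "baseline_window_s",
              "stim_auc_long_s", "stim_auc_short_s"))
    check_window(cfg[[w]], w)
  if (cfg$smoothing_window_s <= 0)
    stopf("pipeline_config: smoothing_window_s must be > 0")
  if (!is.null(cfg$lowpass_hz) && cfg$lowpass_hz <= 0)
    stopf("pipeline_config: lowpass_hz must be > 0 or NULL")
  if (cfg$subject_cv < 0) stopf("pipeline_config: subject_cv must be >= 0")
  validate_task_config(cfg$task)
  validate_task_config(cfg$omission_task)
  validate_ground_truth(cfg$truth)
  miss <- setdiff(cfg$conditions, names(cfg$condition_scales))
  if (length(miss))
    stopf("pipeline_config: no scale factor for condition(s) %s",
          paste(miss, collapse = ", "))
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("Pipeline config [%s]: %d subjects x %d sessions at %g Hz, seed %d\n",
              x$region, x$n_subjects, x$n_sessions, x$fs, x$seed))
  cat(sprintf("  AUC window [%g, %g] s; dip window [%g, %g] s; baseline [%g, %g] s\n",
              x$auc_window_s[1], x$auc_window_s[2], x$omission_window_s[1],
              x$omission_window_s[2], x$baseline_window_s[1],
              x$baseline_window_s[2]))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a validated [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$task <- unclass(x$task)
  x$omission_task <- unclass(x$omission_task)
  x$truth <- unclass(x$truth)
  x$condition_scales <- as.list(x$condition_scales)  # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$task <- do.call(task_config, x$task)
  x$omission_task <- do.call(task_config, x$omission_task)
  x$truth <- do.call(ground_truth, x$truth)
  x$condition_scales <- unlist(x$condition_scales)
  for (w in c("auc_window_s", "omission_window_s", "baseline_window_s",
              "stim_auc_long_s", "stim_auc_short_s"))
    x[[w]] <- as.numeric(x[[w]])
  do.call(pipeline_config, x)
}

# Ground truth for one subject: multiplicative amplitude factor.
subject_truth <- function(truth, factor, condition_scale = NULL) {
  truth$a_max <- truth$a_max * factor
  truth$nonlaser_amplitude <- truth$nonlaser_amplitude * factor
  truth$stim_amplitude <- truth$stim_amplitude * factor
  truth$dip_amplitude <- truth$dip_amplitude * factor
  if (!is.null(condition_scale)) truth$condition_scale <- condition_scale
  truth
}

subject_factors <- function(n, cv, seed) {
  if (cv <= 0) return(rep(1, n))
  with_seed(seed, pmax(0.2, rnorm(n, 1, cv)))
}

# Simulate one session and return its dF/F0 trace plus schedule.
sim_session_dff <- function(task, kernel, truth, fs, seed, session_index,
                            lowpass_hz = NULL) {
  sched <- generate_schedule(task, seed = seed, session_index = session_index)
  sim <- simulate_traces(sched, kernel, truth, fs = fs, seed = seed + 1L,
                         session_index = session_index)
  dff <- compute_dff(sim$trace)
  if (!is.null(lowpass_hz)) dff <- lowpass_dff(dff, lowpass_hz)
  list(schedule = sched, dff = dff, manifest = sim$manifest)
}

#' Run the full synthetic experiment pipeline
#'
#' Simulates and analyzes a replicate-style experiment, deterministically
#' given `config$seed`:
#'
#' * `learning` — per-subject training sessions; cue-aligned AUC learning
#'   curve ([session_curve()]) and its two-way RM ANOVA.
#' * `omission` — omission sessions; per-subject dip AUC
#'   ([omission_auc()]) and the one-sample t test against 0.
#' * `kinetics` — omission sessions in two region presets; per-subject
#'   zero-crossing points for stimulation- and cue-aligned traces and
#'   unpaired t comparisons.
#' * `conditions` — terminal-stimulation sessions: freely-moving vs
#'   anesthetized paired t (0--20 s AUC) and the drug condition one-way RM
#'   ANOVA with Tukey post hoc (0--5 s AUC).
#'
#' When `out_dir` is given, writes `auc_curve.csv`, `omission.csv`,
#' `kinetics.csv`, `stats.json` and `provenance.yaml` (all stamped with the
#' seed and a config hash).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param components Subset of
#'   `c("learning", "omission", "kinetics", "conditions")`.
#' @return A list of class `pipeline_result` with per-component tables and
#'   `stat_result` objects, plus `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         components = c("learning", "omission", "kinetics",
                                        "conditions")) {
  validate_pipeline_config(config)
  components <- match.arg(components, several.ok = TRUE)
  t_start <- proc.time()[["elapsed"]]
  res <- list(provenance = list(seed = config$seed,
                                config_hash = config_hash(unclass(config)),
                                package_version = as.character(utils::packageVersion("optopav"))))
  kern <- region_kernel(config$region)
  sfac <- subject_factors(config$n_subjects, config$subject_cv,
                          child_seed(config$seed, 1))

  log_stage <- function(name) {
    message(sprintf("[optopav] %-10s t=%.1fs", name,
                    proc.time()[["elapsed"]] - t_start))
  }

  if ("learning" %in% components) {
    log_stage("learning")
    rows <- list()
    for (subj in seq_len(config$n_subjects)) {
      truth_s <- subject_truth(config$truth, sfac[subj])
      for (ses in seq_len(config$n_sessions)) {
        sd0 <- child_seed(config$seed, 100 + subj * 50 + ses)
        out <- sim_session_dff(config$task, kern, truth_s, config$fs, sd0,
                               ses, config$lowpass_hz)
        win <- c(config$baseline_window_s[1],
                 max(config$auc_window_s[2] + 0.5, 2))
        tens <- align_trials(out$dff, out$schedule, "cue_onset",
                             window_s = win,
                             baseline_window_s = config$baseline_window_s)
        auc <- trial_auc(tens, config$auc_window_s)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, session = ses, type = tens$trial_type,
          trial_index = tens$trial_index, auc = auc)
      }
    }
    auc_table <- do.call(rbind, rows)
    curve <- session_curve(auc_table)
    anova_df <- data.frame(subject = curve$subject, session = curve$session,
                           cue = curve$type, value = curve$auc)
    res$learning <- list(auc_table = auc_table, curve = curve,
                         anova = two_way_rm_anova(anova_df))
  }

  if (any(c("omission", "kinetics") %in% components)) {
    log_stage("omission")
    om_session <- config$n_sessions + 1L
    omission_sims <- lapply(seq_len(config$n_subjects), function(subj) {
      truth_s <- subject_truth(config$truth, sfac[subj])
      sd0 <- child_seed(config$seed, 5000 + subj)
      sim_session_dff(config$omission_task, kern, truth_s, config$fs, sd0,
                      om_session, config$lowpass_hz)
    })
    if ("omission" %in% components) {
      # Baseline precedes the cue (not just the expected laser) so the
      # phasic cue transient cannot leak into the dip estimate.
      delay <- config$omission_task$laser_delay_s
      om_base <- config$baseline_window_s - delay
      dip_auc <- vapply(omission_sims, function(out) {
        tens <- align_trials(out$dff, out$schedule, "omission_expected_laser",
                             window_s = c(om_base[1],
                                          config$omission_window_s[2] + 1),
                             baseline_window_s = om_base)
        omission_auc(tens, config$omission_window_s)
      }, numeric(1))
      res$omission <- list(
        auc = data.frame(subject = seq_len(config$n_subjects), auc = dip_auc),
        t_test = one_sample_t(dip_auc))
    }
  }

  if ("kinetics" %in% components) {
    log_stage("kinetics")
    om_session <- config$n_sessions + 1L
    per_region <- lapply(config$kinetics_regions, function(region) {
      kern_r <- region_kernel(region)
      lapply(seq_len(config$n_subjects), function(subj) {
        if (region == config$region) {
          out <- omission_sims[[subj]]
        } else {
          truth_s <- subject_truth(config$truth, sfac[subj])
          sd0 <- child_seed(config$seed, 7000 + subj + match(region, config$kinetics_regions) * 100)
          out <- sim_session_dff(config$omission_task, kern_r, truth_s,
                                 config$fs, sd0, om_session, config$lowpass_hz)
        }
        stim <- align_trials(out$dff, out$schedule, "laser_onset",
                             window_s = c(-2, 12),
                             baseline_window_s = config$baseline_window_s)
        omis <- align_trials(out$dff, out$schedule, "cue_onset",
                             window_s = c(-2, 12),
                             baseline_window_s = config$baseline_window_s,
                             types = "omission")
        list(stim = tensor_zero_crossings(stim, 0, config$smoothing_window_s),
             omission = tensor_zero_crossings(omis, 0, config$smoothing_window_s))
      })
    })
    names(per_region) <- config$kinetics_regions
    tab <- do.call(rbind, lapply(config$kinetics_regions, function(region) {
      do.call(rbind, lapply(seq_len(config$n_subjects), function(subj) {
        r <- per_region[[region]][[subj]]
        data.frame(region = region, subject = subj,
                   stim_point_a_s = r$stim$point_a_s,
                   omission_point_a_s = r$omission$point_a_s,
                   omission_point_b_s = r$omission$point_b_s)
      }))
    }))
    g <- function(region, which) lapply(per_region[[region]], `[[`, which)
    r1 <- config$kinetics_regions[1]
    r2 <- config$kinetics_regions[2]
    res$kinetics <- list(
      table = tab,
      stim_point_a = compare_regions(g(r1, "stim"), g(r2, "stim"), "a",
                                     labels = c(r1, r2)),
      omission_point_a = compare_regions(g(r1, "omission"), g(r2, "omission"),
                                         "a", labels = c(r1, r2)),
      omission_point_b = compare_regions(g(r1, "omission"), g(r2, "omission"),
                                         "b", labels = c(r1, r2)))
  }

  if ("conditions" %in% components) {
    log_stage("conditions")
    res$conditions <- run_condition_experiment(config)
  }

  log_stage("done")
  res$provenance$components <- components
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

# Terminal-stimulation experiments (orexin cohort): locomotion control and
# receptor-antagonist conditions.
run_condition_experiment <- function(config) {
  terminal_task <- task_config(
    cue_duration_s = config$task$laser_duration_s,
    laser_delay_s = 0,
    laser_duration_s = config$task$laser_duration_s,
    pulse_rate_hz = config$task$pulse_rate_hz,
    pulse_width_s = config$task$pulse_width_s,
    iti_low_s = config$task$iti_low_s, iti_high_s = config$task$iti_high_s,
    n_laser_trials = config$n_stim_trials, n_nonlaser_trials = 0,
    max_run_length = max(config$task$max_run_length, config$n_stim_trials),
    n_pulses_terminal = config$task$n_pulses_terminal)
  kern <- region_kernel("LH_orexin")
  n <- config$n_subjects_terminal
  sfac <- subject_factors(n, config$subject_cv, child_seed(config$seed, 11))

  stim_auc <- function(subj, cond, offset) {
    truth_s <- subject_truth(config$truth, sfac[subj],
                             condition_scale = unname(config$condition_scales[[cond]]))
    truth_s$a_max <- 0           # no cue learning in terminal sessions
    truth_s$nonlaser_amplitude <- 0
    sd0 <- child_seed(config$seed, offset + subj)
    out <- sim_session_dff(terminal_task, kern, truth_s, config$fs, sd0, 1L,
                           config$lowpass_hz)
    tens <- align_trials(out$dff, out$schedule, "laser_onset",
                         window_s = c(config$baseline_window_s[1],
                                      config$stim_auc_long_s[2] + 2),
                         baseline_window_s = config$baseline_window_s)
    c(long = mean(trial_auc(tens, config$stim_auc_long_s)),
      short = mean(trial_auc(tens, config$stim_auc_short_s)))
  }

  # locomotion control: freely moving vs anesthetized, AUC 0-20 s
  loco <- lapply(c("freely_moving", "anesthetized"), function(cond) {
    vapply(seq_len(n), function(s)
      stim_auc(s, cond, 20000 + 1000 * match(cond, c("freely_moving", "anesthetized")))["long"],
      numeric(1))
  })
  names(loco) <- c("freely_moving", "anesthetized")

  # drug conditions, AUC 0-5 s, within-subject
  drug_rows <- do.call(rbind, lapply(config$conditions, function(cond) {
    data.frame(subject = seq_len(n), condition = cond,
               value = vapply(seq_len(n), function(s)
                 stim_auc(s, cond, 30000 + 1000 * match(cond, config$conditions))["short"],
                 numeric(1)))
  }))

  list(locomotion = list(auc = loco,
                         t_test = paired_t(loco$freely_moving, loco$anesthetized)),
       drug = list(table = drug_rows,
                   anova = one_way_rm_anova(drug_rows, posthoc = TRUE)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result (seed %d, config %s)\n", x$provenance$seed,
              x$provenance$config_hash))
  if (!is.null(x$learning)) {
    cat("\n-- Learning curve ANOVA --\n")
    print(x$learning$anova)
  }
  if (!is.null(x$omission)) {
    cat("\n-- Omission dip --\n")
    print(x$omission$t_test)
  }
  if (!is.null(x$kinetics)) {
    cat("\n-- Kinetics (stimulation point A) --\n")
    print(x$kinetics$stim_point_a)
  }
  if (!is.null(x$conditions)) {
    cat("\n-- Drug conditions --\n")
    print(x$conditions$drug$anova)
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- res$provenance
  stamp <- function(df) {
    df$seed <- prov$seed
    df$config_hash <- prov$config_hash
    df
  }
  if (!is.null(res$learning))
    write.csv(stamp(as.data.frame(res$learning$curve)),
              file.path(out_dir, "auc_curve.csv"), row.names = FALSE)
  if (!is.null(res$omission))
    write.csv(stamp(res$omission$auc), file.path(out_dir, "omission.csv"),
              row.names = FALSE)
  if (!is.null(res$kinetics))
    write.csv(stamp(res$kinetics$table), file.path(out_dir, "kinetics.csv"),
              row.names = FALSE)
  stats_out <- list(provenance = prov)
  if (!is.null(res$learning)) stats_out$learning_anova <- unclass(res$learning$anova)
  if (!is.null(res$omission)) stats_out$omission_t <- unclass(res$omission$t_test)
  if (!is.null(res$kinetics)) {
    stats_out$kinetics_stim_point_a <- unclass(res$kinetics$stim_point_a)
    stats_out$kinetics_omission_point_a <- unclass(res$kinetics$omission_point_a)
    stats_out$kinetics_omission_point_b <- unclass(res$kinetics$omission_point_b)
  }
  if (!is.null(res$conditions)) {
    stats_out$locomotion_paired_t <- unclass(res$conditions$locomotion$t_test)
    stats_out$drug_anova <- unclass(res$conditions$drug$anova)
  }
  drop_null <- function(x) {
    if (is.list(x)) {
      x <- lapply(x[!vapply(x, is.null, logical(1))], drop_null)
    }
    x
  }
  jsonlite::write_json(drop_null(stats_out), file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  write_pipeline_config(config, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}
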