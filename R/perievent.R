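#' Align a dF/F0 trace to schedule events
#'
#' Cuts the trace into a trials x samples matrix on a common relative time
#' grid (half-open window `[lo, hi)`, linear interpolation onto the grid)
#' and subtracts each trial's own baseline-window mean. Alignment events:
#' `cue_onset` (any trial type), `laser_onset` (laser-paired trials) or
#' `omission_expected_laser` (omission trials; the expected laser onset is
#' cue onset + laser delay). Trials whose window does not fit inside the
#' recording are dropped with a warning; if all trials drop, the call fails.
#'
#' @param dff A [dff_trace()].
#' @param schedule An `event_schedule`.
#' @param event_label Alignment event.
#' @param window_s `(lo, hi)` window around the event, seconds (half-open).
#' @param baseline_window_s `(lo, hi)` baseline window, seconds; must end at
#'   or before 0.
#' @param types Optional subset of trial types to align (defaults to the
#'   types natural for the event).
#' @param expected_laser_delay_s Laser delay used for
#'   `omission_expected_laser` when the schedule has no laser trials and no
#'   config attribute.
#' @return A `perievent_tensor`: list with `data` (trials x samples matrix),
#'   `rel_t`, `event_label`, `baseline_window_s`, `trial_index`,
#'   `trial_type`, `fs`.
#' @export
align_trials <- function(dff, schedule,
                         event_label = c("cue_onset", "laser_onset",
                                         "omission_expected_laser"),
                         window_s = c(-2, 10),
                         baseline_window_s = c(-2, 0),
                         types = NULL,
                         expected_laser_delay_s = NULL) {
  if (!inherits(dff, "dff_trace")) stopf("`dff` must be a dff_trace")
  event_label <- match.arg(event_label)
  check_window(window_s, "window_s")
  check_window(baseline_window_s, "baseline_window_s")
  if (baseline_window_s[2] > 0)
    stopf("baseline window must precede the alignment event (hi <= 0)")
  if (baseline_window_s[1] < window_s[1] || baseline_window_s[2] > window_s[2])
    stopf("baseline window must lie inside `window_s`")

  ev <- event_times(schedule, event_label, types, expected_laser_delay_s)
  if (!nrow(ev)) stopf("no trials match event '%s'", event_label)

  fs <- dff$fs
  m <- ceiling((window_s[2] - window_s[1]) * fs - 1e-9)
  rel_t <- window_s[1] + (seq_len(m) - 1) / fs

  t0 <- dff$t[1]
  tn <- dff$t[length(dff$t)]
  keep <- ev$t_s + rel_t[1] >= t0 & ev$t_s + rel_t[m] <= tn
  if (any(!keep))
    warnf("dropping %d trial(s) whose peri-event window falls outside the recording (trials %s)",
          sum(!keep), paste(ev$trial_index[!keep], collapse = ", "))
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) stopf("all trials dropped: no peri-event window fits the recording")

  # Uniform-grid linear interpolation, vectorized over the whole tensor.
  dt <- 1 / fs
  pos <- outer(ev$t_s - t0, rel_t, "+") / dt  # fractional sample index (0-based)
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- pmin(pmax(i0, 0), length(dff$t) - 2L)
  y <- dff$dff
  mat <- y[i0 + 1L] * (1 - frac) + y[i0 + 2L] * frac
  dim(mat) <- dim(pos)

  bsel <- rel_t >= baseline_window_s[1] & rel_t < baseline_window_s[2]
  if (!any(bsel)) stopf("baseline window contains no samples at fs = %g", fs)
  mat <- mat - rowMeans(mat[, bsel, drop = FALSE])

  structure(list(data = mat, rel_t = rel_t, event_label = event_label,
                 baseline_window_s = baseline_window_s,
                 trial_index = ev$trial_index, trial_type = ev$trial_type,
                 fs = fs),
            class = "perievent_tensor")
}

# Event times for each alignment label.
event_times <- function(schedule, event_label, types = NULL,
                        expected_laser_delay_s = NULL) {
  df <- as.data.frame(schedule)
  if (event_label == "cue_onset") {
    if (is.null(types)) types <- TRIAL_TYPES
    df <- df[df$type %in% types, , drop = FALSE]
    data.frame(trial_index = df$trial_index, trial_type = df$type,
               t_s = df$cue_onset_s)
  } else if (event_label == "laser_onset") {
    df <- df[df$type == "laser_paired", , drop = FALSE]
    data.frame(trial_index = df$trial_index, trial_type = df$type,
               t_s = df$laser_onset_s)
  } else {
    om <- df[df$type == "omission", , drop = FALSE]
    if (is.null(expected_laser_delay_s)) {
      cfg <- attr(schedule, "config")
      if (!is.null(cfg)) {
        expected_laser_delay_s <- cfg$laser_delay_s
      } else if (any(df$type == "laser_paired")) {
        las <- df[df$type == "laser_paired", ]
        expected_laser_delay_s <- stats::median(las$laser_onset_s - las$cue_onset_s)
      } else {
        expected_laser_delay_s <- 2
      }
    }
    data.frame(trial_index = om$trial_index, trial_type = om$type,
               t_s = om$cue_onset_s + expected_laser_delay_s)
  }
}

#' @export
print.perievent_tensor <- function(x, ...) {
  cat(sprintf("perievent_tensor: %d trials x %d samples, aligned to %s, rel_t [%.2f, %.2f) s\n",
              nrow(x$data), ncol(x$data), x$event_label, min(x$rel_t),
              max(x$rel_t) + 1 / x$fs))
  cat(sprintf("  baseline window [%g, %g) s; types: %s\n",
              x$baseline_window_s[1], x$baseline_window_s[2],
              paste(unique(x$trial_type), collapse = ", ")))
  invisible(x)
}

#' @export
plot.perievent_tensor <- function(x, ...) {
  mu <- colMeans(x$data)
  sem <- apply(x$data, 2, sd) / sqrt(nrow(x$data))
  plot(x$rel_t, mu, type = "n", xlab = "time from event (s)",
       ylab = expression(Delta * F / F[0]),
       ylim = range(c(mu - sem, mu + sem)), ...)
  polygon(c(x$rel_t, rev(x$rel_t)), c(mu + sem, rev(mu - sem)),
          col = "grey85", border = NA)
  lines(x$rel_t, mu)
  abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Per-trial windowed area under the curve
#'
#' Trapezoidal integral of each tensor row over the closed window
#' `[lo, hi]` of relative time, in dF/F0 x seconds; may be negative (dips).
#'
#' @param tensor A `perievent_tensor`.
#' @param window_s `(lo, hi)` integration window, seconds.
#' @return Numeric vector, one AUC per trial.
#' @export
trial_auc <- function(tensor, window_s = c(0, 1.5)) {
  if (!inherits(tensor, "perievent_tensor")) stopf("`tensor` must be a perievent_tensor")
  check_window(window_s, "window_s")
  sel <- tensor$rel_t >= window_s[1] - 1e-9 & tensor$rel_t <= window_s[2] + 1e-9
  if (sum(sel) < 2)
    stopf("empty AUC window [%g, %g]: fewer than 2 samples inside rel_t",
          window_s[1], window_s[2])
  tt <- tensor$rel_t[sel]
  unname(apply(tensor$data[, sel, drop = FALSE], 1,
               function(row) pracma::trapz(tt, row)))
}

#' Subject-level omission-dip AUC
#'
#' Mean over omission trials of the per-trial AUC in the dip window after
#' the expected laser onset. Expected to be negative when a dip is present.
#'
#' @param tensor A `perievent_tensor` aligned to `omission_expected_laser`
#'   (omission trials only).
#' @param window_s Dip window, seconds after the expected laser onset.
#' @return A single AUC value (dF/F0 x s) for the subject.
#' @export
omission_auc <- function(tensor, window_s = c(0, 2)) {
  if (!inherits(tensor, "perievent_tensor")) stopf("`tensor` must be a perievent_tensor")
  if (nrow(tensor$data) == 0) stopf("no omission trials in tensor")
  if (!all(tensor$trial_type == "omission"))
    stopf("omission_auc requires a tensor built from omission trials only")
  mean(trial_auc(tensor, window_s))
}

#' Session learning curve of cue-evoked AUC
#'
#' Aggregates a long per-trial AUC table into per-subject, per-session,
#' per-cue-type means — the learning curve that feeds
#' [two_way_rm_anova()]. The table must be complete: every
#' subject x session x type cell must contain at least one trial.
#'
#' @param auc_table Data frame with columns `subject`, `session`, `type`,
#'   `auc` (one row per trial, or already per-cell means).
#' @return Data frame of class `auc_curve` with columns `subject`,
#'   `session`, `type`, `auc` (cell means), sorted.
#' @export
session_curve <- function(auc_table) {
  need <- c("subject", "session", "type", "auc")
  if (!all(need %in% names(auc_table)))
    stopf("auc_table must have columns %s", paste(need, collapse = ", "))
  agg <- stats::aggregate(auc ~ subject + session + type, data = auc_table,
                          FUN = mean)
  full <- expand.grid(subject = unique(auc_table$subject),
                      session = unique(auc_table$session),
                      type = unique(auc_table$type),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$session, d$type, sep = "|")
  missing <- setdiff(key(full), key(agg))
  if (length(missing))
    stopf("missing cells in AUC table: %s", paste(missing, collapse = "; "))
  agg <- agg[order(agg$subject, agg$session, agg$type), ]
  rownames(agg) <- NULL
  class(agg) <- c("auc_curve", "data.frame")
  agg
}

#' @export
plot.auc_curve <- function(x, ...) {
  wide <- stats::aggregate(auc ~ session + type, data = x, FUN = mean)
  types <- unique(wide$type)
  cols <- seq_along(types)
  plot(range(wide$session), range(wide$auc), type = "n",
       xlab = "session", ylab = "AUC (dF/F0 x s)", ...)
  for (i in seq_along(types)) {
    d <- wide[wide$type == types[i], ]
    lines(d$session, d$auc, col = cols[i], type = "b", pch = 16)
  }
  legend("topleft", legend = types, col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}
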