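#' Smoothed temporal derivative of a mean trace
#'
#' Moving-average smoothing (symmetric window, shrinking one-sidedly at the
#' edges) followed by a central finite difference; edge samples use one-sided
#' differences so the output length equals the input length. Units:
#' dF/F0 per second.
#'
#' @param x Numeric series (typically the trial-mean peri-event trace).
#' @param fs Sampling rate, Hz.
#' @param smoothing_window_s Moving-average window in seconds; must span at
#'   least 3 samples and at most the trace length. Rounded to an odd sample
#'   count.
#' @return Numeric series of the same length as `x`.
#' @examples
#' trace_derivative(seq(0, 1, by = 0.01) * 3, fs = 100,
#'                  smoothing_window_s = 0.05)  # ~3 everywhere inside
#' @export
trace_derivative <- function(x, fs, smoothing_window_s = 0.5) {
  n <- length(x)
  w <- round(smoothing_window_s * fs)
  if (w < 3) stopf("smoothing window must cover at least 3 samples (got %d)", w)
  if (w %% 2 == 0) w <- w + 1L
  if (w > n) stopf("smoothing window (%d samples) longer than trace (%d samples)", w, n)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) * fs / 2
  d[1] <- (sm[2] - sm[1]) * fs
  d[n] <- (sm[n] - sm[n - 1]) * fs
  d
}

#' Zero crossings of a derivative after a reference time
#'
#' Scans the derivative series for its first positive-to-negative sign
#' change after `t_ref` (point A, the trace maximum) and the first
#' subsequent negative-to-positive change (point B, the trace minimum).
#' Crossing times are located at sub-sample resolution by linear
#' interpolation between the bracketing samples. Zero-valued samples are
#' bridged: a transition is detected between the nearest non-zero samples
#' of opposite sign. If the derivative is never positive after `t_ref`,
#' point A is reported absent (a valid no-crossing result, not an error).
#'
#' @param deriv Derivative series (e.g. from [trace_derivative()]).
#' @param rel_t Time axis of `deriv`, seconds.
#' @param t_ref Reference time; crossings are searched strictly after it.
#' @param reference_label Free-text label stored in the result.
#' @param smoothing_window_s Smoothing window used upstream (metadata).
#' @return A `zero_crossing_result`: list with `point_a_s`, `point_b_s`
#'   (seconds after `t_ref`; `NA` when absent), `reference_label`,
#'   `smoothing_window_s`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' find_zero_crossings(cos(2 * pi * t), t, 0)  # A = 0.25, B = 0.75
#' @export
find_zero_crossings <- function(deriv, rel_t, t_ref = 0,
                                reference_label = "",
                                smoothing_window_s = NA_real_) {
  if (length(deriv) != length(rel_t)) stopf("deriv and rel_t lengths differ")
  if (t_ref < min(rel_t) || t_ref > max(rel_t))
    stopf("t_ref = %g outside rel_t range [%g, %g]", t_ref, min(rel_t), max(rel_t))

  start <- which(rel_t >= t_ref)[1]
  idx <- start:length(deriv)
  d <- deriv[idx]
  tt <- rel_t[idx]

  nz <- which(d != 0)
  point_a <- NA_real_
  point_b <- NA_real_
  if (length(nz) >= 2) {
    s <- sign(d[nz])
    trans <- which(s[-1] != s[-length(s)])
    for (k in trans) {
      p <- nz[k]
      q <- nz[k + 1]
      # interpolate between the bracketing non-zero samples
      tc <- tt[p] + d[p] / (d[p] - d[q]) * (tt[q] - tt[p])
      if (tc <= t_ref) next
      if (is.na(point_a)) {
        if (s[k] > 0) point_a <- tc
      } else if (s[k] < 0) {
        point_b <- tc
        break
      }
    }
  }
  structure(list(point_a_s = if (is.na(point_a)) NA_real_ else point_a - t_ref,
                 point_b_s = if (is.na(point_b)) NA_real_ else point_b - t_ref,
                 reference_label = reference_label,
                 smoothing_window_s = smoothing_window_s),
            class = "zero_crossing_result")
}

#' @export
print.zero_crossing_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.3f s", v)
  cat(sprintf("Zero crossings after %s: point A %s, point B %s (smoothing %s)\n",
              if (nzchar(x$reference_label)) x$reference_label else "reference",
              fmt(x$point_a_s), fmt(x$point_b_s),
              if (is.na(x$smoothing_window_s)) "n/a"
              else sprintf("%g s", x$smoothing_window_s)))
  invisible(x)
}

#' Peri-event kinetics of a subject-mean trace
#'
#' Convenience wrapper: trial-mean of a peri-event tensor, smoothed
#' derivative, zero-crossing detection after `t_ref`.
#'
#' @param tensor A `perievent_tensor`.
#' @param t_ref Reference time on the tensor's relative axis.
#' @param smoothing_window_s Moving-average window, seconds.
#' @return A `zero_crossing_result`.
#' @export
tensor_zero_crossings <- function(tensor, t_ref = 0, smoothing_window_s = 0.5) {
  mu <- colMeans(tensor$data)
  d <- trace_derivative(mu, tensor$fs, smoothing_window_s)
  find_zero_crossings(d, tensor$rel_t, t_ref,
                      reference_label = tensor$event_label,
                      smoothing_window_s = smoothing_window_s)
}

#' Compare zero-crossing kinetics between two groups of subjects
#'
#' Unpaired Student's t test on per-subject crossing times (point A by
#' default, or point B). Subjects with an absent crossing are excluded with
#' a warning; the comparison fails if a group empties.
#'
#' @param group_a,group_b Lists of `zero_crossing_result` (one per subject).
#' @param point `"a"` or `"b"`.
#' @param labels Group labels for the report.
#' @return A `stat_result` from [unpaired_t()] with group means attached.
#' @export
compare_regions <- function(group_a, group_b, point = c("a", "b"),
                            labels = c("group_a", "group_b")) {
  point <- match.arg(point)
  field <- paste0("point_", point, "_s")
  pull <- function(g, lab) {
    v <- vapply(g, function(r) r[[field]], numeric(1))
    if (anyNA(v)) {
      warnf("excluding %d subject(s) with absent point %s in %s",
            sum(is.na(v)), toupper(point), lab)
      v <- v[!is.na(v)]
    }
    v
  }
  va <- pull(group_a, labels[1])
  vb <- pull(group_b, labels[2])
  if (length(va) < 2 || length(vb) < 2)
    stopf("need >= 2 subjects with detected crossings per group (got %d and %d)",
          length(va), length(vb))
  res <- unpaired_t(va, vb)
  res$test_name <- sprintf("unpaired t on zero-crossing point %s (%s vs %s)",
                           toupper(point), labels[1], labels[2])
  res$group_means <- setNames(c(mean(va), mean(vb)), labels)
  res
}
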