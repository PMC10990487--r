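# Statistical layer: thin, structured wrappers around stats::t.test and
# stats::aov that return a uniform `stat_result` and handle the degenerate
# zero-variance cases explicitly.

new_stat_result <- function(test_name, statistic, df, p_value,
                            direction = NA_real_, estimate = NA_real_,
                            posthoc = NULL, n = NA_integer_,
                            degenerate = FALSE) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, direction = direction,
                 estimate = estimate, posthoc = posthoc, n = n,
                 degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name, "\n")
  if (length(x$statistic) == 1 && is.null(names(x$statistic))) {
    dfs <- paste(format(x$df, digits = 4), collapse = ", ")
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g%s\n", x$statistic, dfs,
                x$p_value, if (isTRUE(x$degenerate)) " [degenerate: zero variance]" else ""))
  } else {
    for (nm in names(x$statistic)) {
      df <- x$df[[nm]]
      cat(sprintf("  %s: F(%g, %g) = %.4g, p = %.4g\n", nm, df[1], df[2],
                  x$statistic[[nm]], x$p_value[[nm]]))
    }
  }
  if (!is.null(x$posthoc)) {
    cat("  Tukey post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

# Shared degenerate-case handling for t tests on a single vector of
# (differences from) mu0.
t_core <- function(v, mu0, df, test_name, n_label) {
  m <- mean(v)
  if (sd(v) == 0) {
    if (m == mu0)
      return(new_stat_result(test_name, 0, df, 1, direction = 0,
                             estimate = m, n = n_label, degenerate = TRUE))
    return(new_stat_result(test_name, sign(m - mu0) * Inf, df, 0,
                           direction = sign(m - mu0), estimate = m,
                           n = n_label, degenerate = TRUE))
  }
  NULL
}

#' One-sample t test
#'
#' Two-sided Student's t test of `mean(values) == mu0`, df = n - 1. A
#' zero-variance sample with mean different from `mu0` is flagged as a
#' degenerate infinite-t result rather than an error.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null mean.
#' @return A `stat_result`.
#' @examples
#' one_sample_t(c(1, 2, 3, 4))  # df = 3
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2) stopf("need n >= 2 values")
  deg <- t_core(values, mu0, length(values) - 1L, "one-sample t test",
                length(values))
  if (!is.null(deg)) return(deg)
  ht <- t.test(values, mu = mu0)
  new_stat_result("one-sample t test", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  direction = sign(mean(values) - mu0),
                  estimate = mean(values), n = length(values))
}

#' Two-sample Student's t tests
#'
#' `unpaired_t` is the pooled-variance (Student) two-sided test with
#' df = n_a + n_b - 2; `paired_t` tests the paired differences with
#' df = n - 1. Zero-variance cases are flagged as degenerate.
#'
#' @param group_a,group_b Numeric vectors (length >= 2; equal length for
#'   the paired test).
#' @return A `stat_result`.
#' @examples
#' unpaired_t(rnorm(4), rnorm(4))  # df = 6
#' @export
unpaired_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("need n >= 2 per group")
  df <- length(group_a) + length(group_b) - 2L
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    d <- mean(group_a) - mean(group_b)
    return(new_stat_result("unpaired t test (pooled variance)",
                           if (d == 0) 0 else sign(d) * Inf, df,
                           if (d == 0) 1 else 0, direction = sign(d),
                           estimate = d,
                           n = c(length(group_a), length(group_b)),
                           degenerate = TRUE))
  }
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  new_stat_result("unpaired t test (pooled variance)", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  direction = sign(mean(group_a) - mean(group_b)),
                  estimate = mean(group_a) - mean(group_b),
                  n = c(length(group_a), length(group_b)))
}

#' @rdname unpaired_t
#' @export
paired_t <- function(group_a, group_b) {
  if (length(group_a) != length(group_b)) stopf("paired inputs must have equal length")
  if (length(group_a) < 2) stopf("need n >= 2 pairs")
  d <- group_a - group_b
  deg <- t_core(d, 0, length(d) - 1L, "paired t test", length(d))
  if (!is.null(deg)) return(deg)
  ht <- t.test(group_a, group_b, paired = TRUE)
  new_stat_result("paired t test", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, direction = sign(mean(d)), estimate = mean(d),
                  n = length(d))
}

check_rm_table <- function(df, factors) {
  need <- c("subject", factors, "value")
  if (!all(need %in% names(df)))
    stopf("table must have columns %s", paste(need, collapse = ", "))
  cells <- do.call(table, df[c("subject", factors)])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)
    labs <- apply(idx, 1, function(r)
      paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                   seq_along(r), r), collapse = "/"))
    stopf("missing cells (subject/%s): %s", paste(factors, collapse = "/"),
          paste(labs, collapse = "; "))
  }
  if (any(cells > 1))
    stopf("table must hold one value per subject x %s cell",
          paste(factors, collapse = " x "))
  invisible(df)
}

# Pull the F row for `term` from a summary.aovlist, with the 0/0 -> F = 0
# convention for identically-zero effects.
extract_f <- function(s, term) {
  for (stratum in s) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    if (!is.na(i) && "F value" %in% colnames(tab)) {
      ss_eff <- tab[i, "Sum Sq"]
      f <- tab[i, "F value"]
      p <- tab[i, "Pr(>F)"]
      df1 <- tab[i, "Df"]
      df2 <- tab[nrow(tab), "Df"]
      if (!is.finite(f)) {
        if (ss_eff <= 1e-12) {
          f <- 0
          p <- 1
        } else {
          f <- Inf
          p <- 0
        }
      }
      return(list(f = f, df = c(df1, df2), p = p))
    }
  }
  stopf("term '%s' not found in ANOVA summary", term)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete balanced subject x session x
#' cue-type table (both factors within subject), fitted with
#' `stats::aov` using `Error(subject/(session * cue))` strata. For the
#' standard design (4 subjects, 10 sessions, 2 cues) the session and
#' interaction tests have df = (9, 27). No sphericity correction is
#' applied. Cells where every value is identical yield F = 0, p = 1.
#'
#' @param df Data frame with columns `subject`, `session`, `cue`, `value`
#'   (one value per cell; missing cells are an error, no imputation).
#' @return A `stat_result` with named F statistics, df pairs and p values
#'   for `session`, `cue` and `session:cue`.
#' @export
two_way_rm_anova <- function(df) {
  check_rm_table(df, c("session", "cue"))
  d <- data.frame(subject = factor(df$subject), session = factor(df$session),
                  cue = factor(df$cue), value = df$value)
  if (nlevels(d$session) < 2 || nlevels(d$cue) < 2)
    stopf("two_way_rm_anova: need >= 2 levels of session and cue")
  if (diff(range(d$value)) == 0) {
    # identically constant table: every effect SS is exactly zero
    zero <- c(session = 0, cue = 0, `session:cue` = 0)
    n <- nlevels(d$subject)
    dfs <- list(session = c(nlevels(d$session) - 1,
                            (nlevels(d$session) - 1) * (n - 1)),
                cue = c(nlevels(d$cue) - 1, (nlevels(d$cue) - 1) * (n - 1)),
                `session:cue` = c((nlevels(d$session) - 1) * (nlevels(d$cue) - 1),
                                  (nlevels(d$session) - 1) * (nlevels(d$cue) - 1) * (n - 1)))
    return(new_stat_result(
      "two-way repeated-measures ANOVA (session x cue, within subject)",
      statistic = zero, df = dfs, p_value = c(session = 1, cue = 1, `session:cue` = 1),
      n = n))
  }
  fit <- aov(value ~ session * cue + Error(subject / (session * cue)), data = d)
  s <- summary(fit)
  terms <- c(session = "session", cue = "cue", `session:cue` = "session:cue")
  res <- lapply(terms, function(tm) extract_f(s, tm))
  new_stat_result(
    "two-way repeated-measures ANOVA (session x cue, within subject)",
    statistic = vapply(res, `[[`, numeric(1), "f"),
    df = lapply(res, `[[`, "df"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    n = nlevels(d$subject))
}

#' One-way repeated-measures ANOVA with Tukey post hoc comparisons
#'
#' Within-subject one-way ANOVA on a complete subject x condition table
#' (`stats::aov` with `Error(subject/condition)`), df =
#' (k - 1, (k - 1)(n - 1)). [tukey_posthoc()] computes all pairwise Tukey
#' HSD comparisons from the within-subject error stratum using the
#' studentized range distribution.
#'
#' @param df Data frame with columns `subject`, `condition`, `value`.
#' @param posthoc If `TRUE`, attach the Tukey table.
#' @return A `stat_result` (with `$posthoc` when requested).
#' @export
one_way_rm_anova <- function(df, posthoc = TRUE) {
  check_rm_table(df, "condition")
  d <- data.frame(subject = factor(df$subject),
                  condition = factor(df$condition), value = df$value)
  if (nlevels(d$condition) < 2) stopf("need >= 2 conditions")
  if (diff(range(d$value)) == 0) {
    k <- nlevels(d$condition)
    n <- nlevels(d$subject)
    out <- new_stat_result("one-way repeated-measures ANOVA (condition within subject)",
                           statistic = 0, df = c(k - 1, (k - 1) * (n - 1)),
                           p_value = 1, n = n)
    if (posthoc) out$posthoc <- tukey_posthoc(d)
    return(out)
  }
  fit <- aov(value ~ condition + Error(subject / condition), data = d)
  s <- summary(fit)
  res <- extract_f(s, "condition")
  out <- new_stat_result("one-way repeated-measures ANOVA (condition within subject)",
                         statistic = res$f, df = res$df, p_value = res$p,
                         n = nlevels(d$subject))
  if (posthoc) out$posthoc <- tukey_posthoc(d)
  out
}

#' @rdname one_way_rm_anova
#' @export
tukey_posthoc <- function(df) {
  check_rm_table(df, "condition")
  d <- data.frame(subject = factor(df$subject),
                  condition = factor(df$condition), value = df$value)
  k <- nlevels(d$condition)
  n <- nlevels(d$subject)
  means <- tapply(d$value, d$condition, mean)
  if (diff(range(d$value)) == 0) {
    pairs <- utils::combn(levels(d$condition), 2)
    return(data.frame(comparison = paste(pairs[2, ], "vs", pairs[1, ]),
                      diff = 0, p_adj = 1, stringsAsFactors = FALSE))
  }
  # within-subject error stratum of the RM fit
  fit <- aov(value ~ condition + Error(subject / condition), data = d)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  pairs <- utils::combn(levels(d$condition), 2)
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / n)
  p <- if (is.finite(mse) && mse > 0) {
    ptukey(abs(diff) / se, nmeans = k, df = dfe, lower.tail = FALSE)
  } else {
    ifelse(diff == 0, 1, 0)
  }
  data.frame(comparison = paste(pairs[2, ], "vs", pairs[1, ]),
             diff = unname(diff), p_adj = unname(p),
             stringsAsFactors = FALSE)
}

#' Serialize a stat_result to JSON
#'
#' @param x A `stat_result`.
#' @return A JSON string (pretty-printed).
#' @export
stat_result_json <- function(x) {
  stopifnot(inherits(x, "stat_result"))
  jsonlite::toJSON(unclass(x[!vapply(x, is.null, logical(1))]),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null")
}
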