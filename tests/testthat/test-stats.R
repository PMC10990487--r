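test_that("one-sample t matches a hand calculation and flags degenerate input", {
  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  toy <- one_sample_t(c(1, 2, 3, 4))
  # hand calculation: mean 2.5, sd sqrt(5/3), t = 2.5 / (sd / 2)
  expect_equal(toy$statistic, 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-12)
  expect_equal(toy$df, 3)

  deg <- one_sample_t(rep(2, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, Inf)
  expect_equal(deg$p_value, 0)
  const_null <- one_sample_t(rep(0, 5))
  expect_true(const_null$degenerate)
  expect_equal(const_null$statistic, 0)
})

test_that("two-sample t tests carry the right df and handle degenerate pairs", {
  same <- unpaired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 6)

  pt <- paired_t(c(1, 2, 3), c(0, 1, 2))
  expect_true(pt$degenerate)  # constant difference, zero spread
  expect_equal(pt$statistic, Inf)
  expect_equal(pt$df, 2)
})

test_that("t squared equals the one-way ANOVA F on the same two groups", {
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(6, 0.5)
    tt <- unpaired_t(a, b)
    dat <- data.frame(y = c(a, b), g = rep(c("a", "b"), each = 6))
    f <- anova(stats::lm(y ~ g, dat))[1, "F value"]
    expect_equal(tt$statistic^2, f, tolerance = 1e-8)
  }
})

test_that("two-way RM ANOVA reproduces the standard design df and null edge cases", {
  tab <- expand.grid(subject = 1:4, session = 1:10, cue = c("laser", "non"))
  set.seed(5)
  tab$value <- rnorm(nrow(tab))
  res <- two_way_rm_anova(tab)
  expect_equal(res$df[["session"]], c(9, 27))
  expect_equal(res$df[["cue"]], c(1, 3))
  expect_equal(res$df[["session:cue"]], c(9, 27))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  flat <- tab
  flat$value <- 1
  res0 <- two_way_rm_anova(flat)
  expect_equal(unname(res0$statistic), c(0, 0, 0))
  expect_equal(unname(res0$p_value), c(1, 1, 1))

  expect_error(two_way_rm_anova(tab[-1, ]), "missing cells")
})

test_that("two-way RM sums of squares match a hand-computed decomposition", {
  # 3 subjects x 2 sessions x 2 cues toy table
  tab <- expand.grid(subject = 1:3, session = 1:2, cue = c("A", "B"))
  set.seed(9)
  tab$value <- 0.5 * tab$session + ifelse(tab$cue == "B", 0.3, 0) +
    0.2 * tab$session * (tab$cue == "B") + rnorm(nrow(tab), 0, 0.1)

  res <- two_way_rm_anova(tab)

  # independent oracle: balanced-design SS from marginal means
  g <- mean(tab$value)
  m_s <- tapply(tab$value, tab$session, mean)
  m_c <- tapply(tab$value, tab$cue, mean)
  m_sc <- tapply(tab$value, list(tab$session, tab$cue), mean)
  m_us <- tapply(tab$value, list(tab$subject, tab$session), mean)
  m_uc <- tapply(tab$value, list(tab$subject, tab$cue), mean)
  m_u <- tapply(tab$value, tab$subject, mean)
  n_u <- 3; n_s <- 2; n_c <- 2
  ss_s <- n_u * n_c * sum((m_s - g)^2)
  ss_c <- n_u * n_s * sum((m_c - g)^2)
  ss_sc <- n_u * sum((m_sc - outer(m_s, m_c, "+") + g)^2)
  ss_us <- n_c * sum((m_us - outer(m_u, m_s, "+") + g)^2)
  ss_uc <- n_s * sum((m_uc - outer(m_u, m_c, "+") + g)^2)

  f_session <- (ss_s / (n_s - 1)) / (ss_us / ((n_s - 1) * (n_u - 1)))
  f_cue <- (ss_c / (n_c - 1)) / (ss_uc / ((n_c - 1) * (n_u - 1)))
  expect_equal(unname(res$statistic["session"]), f_session, tolerance = 1e-8)
  expect_equal(unname(res$statistic["cue"]), f_cue, tolerance = 1e-8)
  expect_equal(unname(res$statistic["session:cue"]) > 0, ss_sc > 0)
})

test_that("one-way RM ANOVA df and Tukey behavior", {
  # 4 conditions x 3 subjects reproduces the (3, 6) df structure
  tab <- expand.grid(subject = 1:3,
                     condition = c("no_injection", "vehicle", "SCH23390",
                                   "raclopride"))
  set.seed(2)
  tab$value <- rnorm(nrow(tab))
  res <- one_way_rm_anova(tab)
  expect_equal(res$df, c(3, 6))
  expect_equal(nrow(res$posthoc), 6)

  flat <- tab
  flat$value <- 2
  res0 <- one_way_rm_anova(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_true(all(res0$posthoc$p_adj == 1))
})

test_that("Tukey flags exactly the shifted pairs (Bonferroni-t as conservative oracle)", {
  set.seed(33)
  base <- rnorm(6, 0, 0.05)
  tab <- data.frame(
    subject = rep(1:6, 3),
    condition = rep(c("a", "b", "c"), each = 6),
    value = c(base + rnorm(6, 0, 0.05), base + rnorm(6, 0, 0.05),
              base + 2 + rnorm(6, 0, 0.05)))
  tk <- tukey_posthoc(tab)
  hit <- tk$p_adj < 0.05
  names(hit) <- tk$comparison
  expect_false(hit[["b vs a"]])
  expect_true(hit[["c vs a"]])
  expect_true(hit[["c vs b"]])

  # conservative oracle: all-pairs paired t with Bonferroni correction
  pbonf <- vapply(list(c("b", "a"), c("c", "a"), c("c", "b")), function(pr) {
    min(1, 3 * paired_t(tab$value[tab$condition == pr[1]],
                        tab$value[tab$condition == pr[2]])$p_value)
  }, numeric(1))
  expect_false(pbonf[1] < 0.05)
  expect_true(all(pbonf[2:3] < 0.05))
})

test_that("stat results serialize to JSON", {
  js <- stat_result_json(one_sample_t(c(1, 2, 3, 4)))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$df, 3)
  expect_equal(parsed$test_name, "one-sample t test")
})
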