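fake_table <- function(rt, outcome, rate = 7, cls = NULL, pid = "P") {
  if (is.null(cls)) cls <- ifelse(outcome %in% c("TP", "FN"), "same", "different")
  data.frame(participant_id = pid, class = cls, probe_rate = rate,
             outcome = outcome, rt_ms = rt, trial_index = seq_along(rt),
             stringsAsFactors = FALSE)
}

test_that("RT outlier filter removes only extreme trials, in one pass", {
  # all equal: zero SD, nothing removed
  t1 <- fake_table(rep(1000, 10), rep("TP", 10))
  expect_equal(nrow(filter_rt_outliers(t1)), 10)

  # 19 x 1000 + one 5000: only the extreme trial removed
  t2 <- fake_table(c(rep(1000, 19), 5000), rep("TP", 20))
  f2 <- filter_rt_outliers(t2)
  expect_equal(nrow(f2), 19)
  expect_false(5000 %in% f2$rt_ms)

  # infinite threshold is the identity
  expect_equal(nrow(filter_rt_outliers(t2, k = Inf)), 20)

  # cells are participant x outcome by default: an extreme TN survives a
  # filter pass if its own cell is tight around it
  t3 <- rbind(fake_table(c(rep(1000, 19), 5000), rep("TP", 20)),
              fake_table(rep(4900, 5) + 1:5, rep("TN", 5)))
  f3 <- filter_rt_outliers(t3)
  expect_equal(sum(f3$outcome == "TN"), 5)
})

test_that("outcome tables partition correctly within class and rate", {
  tb <- fake_table(rep(1000, 4), c("TP", "TP", "TP", "FN"))
  ot <- outcome_table(tb)
  expect_equal(ot$pct[ot$outcome == "TP"], 75)
  expect_equal(ot$pct[ot$outcome == "FN"], 25)

  # partition property on a random table
  set.seed(4)
  cls <- sample(c("same", "different"), 300, replace = TRUE)
  resp <- sample(c("same", "different"), 300, replace = TRUE)
  tb2 <- data.frame(participant_id = sample(c("A", "B"), 300, replace = TRUE),
                    class = cls, probe_rate = sample(c(3, 7, 19), 300, TRUE),
                    outcome = classify_outcome(cls, resp),
                    rt_ms = rexp(300) * 1000)
  ot2 <- outcome_table(tb2)
  for (p in c("A", "B")) for (r in c(3, 7, 19)) {
    g <- ot2[ot2$participant_id == p & ot2$probe_rate == r, ]
    expect_equal(g$pct[g$outcome == "TP"] + g$pct[g$outcome == "FN"], 100)
    expect_equal(g$pct[g$outcome == "TN"] + g$pct[g$outcome == "FP"], 100)
  }
  expect_error(outcome_table(tb[0, ]), "empty")
})

test_that("repeated-measures ANOVA has the design dfs and classic behaviour", {
  set.seed(5)
  cube <- array(rnorm(23 * 4 * 3), c(23, 4, 3))
  r <- rm_anova_2way(cube, c("outcome", "rate"))
  expect_equal(r$table$df1, c(3, 2, 6))
  expect_equal(r$table$df2, c(66, 44, 132))
  expect_true(all(r$table$F >= 0))

  # adding a per-participant constant leaves all F values unchanged
  shifted <- cube + rep(rnorm(23) * 50, 4 * 3)
  r2 <- rm_anova_2way(shifted, c("outcome", "rate"))
  expect_equal(r2$table$F, r$table$F, tolerance = 1e-8)

  # a pure constant shift per A level with no noise: p underflows to 0
  pure <- array(rep(rep(c(0, 10, 20, 30), each = 8), 3), c(8, 4, 3))
  rp <- rm_anova_2way(pure + array(rnorm(96, sd = 1e-8), c(8, 4, 3)))
  expect_lt(rp$table$p[1], 1e-10)

  bad <- cube; bad[1, 1, 1] <- NA
  expect_error(rm_anova_2way(bad), "complete")
})

test_that("ANOVA type-I error is nominal under label permutation", {
  set.seed(6)
  n_sim <- 150
  hits <- 0
  for (i in seq_len(n_sim)) {
    cube <- array(rnorm(10 * 4 * 3), c(10, 4, 3))
    r <- rm_anova_2way(cube)
    hits <- hits + (r$table$p[1] < 0.05)
  }
  rate <- hits / n_sim
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("paired t matches the textbook formula and guards degeneracy", {
  x <- c(5.1, 4.8, 6.0, 5.5, 4.9)
  y <- c(4.7, 4.9, 5.2, 5.0, 4.6)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  r <- paired_t_test(x, y)
  expect_equal(r$t, t_manual)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(t_manual), 4))

  expect_equal(paired_t_test(x, x), list(t = 0, df = 4, p = 1))
  r2 <- paired_t_test(x + 1, x)
  expect_identical(r2$t, Inf)
  expect_equal(r2$p, 0)
  # 23 participants -> df 22
  expect_equal(paired_t_test(rnorm(23), rnorm(23))$df, 22)
})

test_that("study-level behaviour stats recover the planted RT ordering", {
  set.seed(7)
  beh <- behavior_params()
  rows <- list()
  for (p in 1:8) {
    sched <- make_trial_schedule(8, seed = p)
    out <- lapply(seq_len(nrow(sched)), function(i)
      simulate_behavior(sched$class[i], sched$probe_rate[i], beh))
    rows[[p]] <- data.frame(
      participant_id = sprintf("P%02d", p), class = sched$class,
      probe_rate = sched$probe_rate,
      outcome = vapply(out, `[[`, "", "outcome"),
      rt_ms = vapply(out, `[[`, 0, "rt_ms"))
  }
  stats <- suppressWarnings(behavior_study_stats(do.call(rbind, rows)))
  fu <- stats$followup_rt
  expect_lt(fu$mean_diff[fu$contrast == "TP vs TN"], 0)   # TP faster than TN
  expect_lt(fu$mean_diff[fu$contrast == "TP vs FP"], 0)   # TP faster than FP
  expect_lt(fu$mean_diff[fu$contrast == "TN vs FN"], 0)   # TN faster than FN
  expect_equal(stats$anova_pct$table$df1, c(3, 2, 6))
  # the 3-Hz same bias: more FPs for 3-Hz than for faster probes
  tab <- stats$table
  fp3 <- mean(tab$pct[tab$outcome == "FP" & tab$probe_rate == 3])
  fp19 <- mean(tab$pct[tab$outcome == "FP" & tab$probe_rate == 19])
  expect_gt(fp3, fp19)
})
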