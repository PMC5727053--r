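test_that("the logical combination satisfies its full truth table", {
  expect_equal(combine_index(TRUE, FALSE), "low")
  expect_equal(combine_index(FALSE, TRUE), "high")
  expect_equal(combine_index(FALSE, FALSE), "moderate")
  expect_equal(combine_index(TRUE, TRUE), "moderate")
  expect_error(combine_index(TRUE, TRUE, conflict = "error"), "conflict")
  # vectorized
  expect_equal(combine_index(c(TRUE, FALSE), c(FALSE, TRUE)),
               c("low", "high"))
})

test_that("task portions are exact percentages summing to 100", {
  series <- data.frame(class = rep(c("high", "low", "moderate"), c(6, 3, 3)))
  p <- task_portions(series)
  expect_equal(c(p$pct_low, p$pct_moderate, p$pct_high), c(25, 25, 50))
  expect_equal(p$n_segments, 12)
  pl <- task_portions(data.frame(class = rep("low", 5)))
  expect_equal(c(pl$pct_low, pl$pct_moderate, pl$pct_high), c(100, 0, 0))
  expect_equal(p$pct_low + p$pct_moderate + p$pct_high, 100, tolerance = 1e-9)
  expect_error(task_portions(data.frame(class = character())), "empty")
  # training-flagged segments are excluded by default
  tr <- data.frame(class = c("high", "low"), training = c(FALSE, TRUE))
  expect_equal(task_portions(tr)$n_segments, 1)
})

test_that("cohort tables keep explicit missing cells", {
  s1 <- data.frame(task_id = c("a", "a", "b"),
                   class = c("low", "low", "high"), training = FALSE)
  s2 <- data.frame(task_id = "a", class = "moderate", training = FALSE)
  tab <- cohort_table(list(S1 = s1, S2 = s2), "pct_high")
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab["S1", "b"], 100)
  expect_true(is.na(tab["S2", "b"]))
})

test_that("two-level repeated-measures ANOVA equals the squared paired t", {
  set.seed(31)
  tab <- matrix(rnorm(24, mean = c(0, 1)), ncol = 2, byrow = TRUE)
  r <- rm_anova_gg(tab)
  tt <- t.test(tab[, 1], tab[, 2], paired = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(r$epsilon, 1)                  # epsilon is 1 by definition at k=2
  expect_equal(nrow(r$pairwise), 1)
  expect_equal(r$pairwise$p_raw, tt$p.value, tolerance = 1e-9)
})

test_that("the ANOVA matches aov and epsilon approaches 1 under sphericity", {
  set.seed(32)
  n <- 300; k <- 4
  tab <- matrix(rnorm(n * k), n, k) + rnorm(n)   # compound symmetric
  tab[, 2] <- tab[, 2] + 0.3
  r <- rm_anova_gg(tab)
  expect_lt(abs(r$epsilon - 1), 0.05)
  # uncorrected F cross-checked against stats::aov
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   lvl = factor(rep(seq_len(k), each = n)))
  fit <- summary(stats::aov(y ~ lvl + Error(subj / lvl), df))
  Faov <- fit[["Error: subj:lvl"]][[1]]["lvl", "F value"]
  expect_equal(r$F, Faov, tolerance = 1e-8)
  # Bonferroni correction multiplies raw p by the family size (capped at 1)
  expect_equal(r$pairwise$p_bonferroni,
               pmin(r$pairwise$p_raw * choose(k, 2), 1))
})

test_that("ANOVA input contracts are enforced", {
  expect_error(rm_anova_gg(matrix(rnorm(8), 2, 4)), "3 subjects")
  expect_error(rm_anova_gg(matrix(rnorm(5), 5, 1)), "2 levels")
  m <- matrix(rnorm(20), 5, 4); m[2, 3] <- NA
  expect_error(rm_anova_gg(m), "incomplete")
})

test_that("the index series covers each segment at the 5 s cadence", {
  set.seed(33)
  mont <- default_montage()
  bat <- mini_battery("block", 300)
  spec <- cohort_spec(1, bat,
                      profiles = list(block = workload_profile(1.8, 0.5, "high")),
                      seed = 44, artifact_rate = 0)
  rec <- generate_recording(spec, 1)
  pr <- process_recording(rec, mont, artifact_policy = "none")
  base <- subject_baseline(pr$segments, bat, subject_id = "S01")
  models <- train_pair(simulate_labeled_dfhm(240, seed = 45))
  series <- workload_index(pr$segments, base, models)
  expect_s3_class(series, "workload_index_series")
  expect_equal(nrow(series), 59)
  expect_equal(unique(diff(series$time_s)), 5)
  expect_true(all(series$class %in% c("low", "moderate", "high")))
  # empty input -> empty series
  expect_equal(nrow(workload_index(list(), base, models)), 0)
  # missing baseline -> directs to the personalization step
  expect_error(workload_index(pr$segments, NULL, models), "fit_baseline")
})
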