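test_that("generation is fully seed-deterministic", {
  bat <- mini_battery("a", 60)
  prof <- list(a = workload_profile(1, 1, "moderate"))
  spec <- cohort_spec(2, bat, prof, seed = 50)
  r1 <- generate_recording(spec, 1)
  r2 <- generate_recording(spec, 1)
  expect_identical(r1$samples, r2$samples)
  # different subjects differ
  expect_false(identical(generate_recording(spec, 2)$samples, r1$samples))
  expect_error(generate_recording(spec, 3), "out of range")
})

test_that("frontal theta band power is monotone in the theta gain", {
  bat <- mini_battery("a", 160)               # 31 segments
  mont <- default_montage()
  powers_for <- function(gain) {
    prof <- list(a = workload_profile(gain, 1, "moderate", grade = gain))
    rec <- generate_recording(cohort_spec(1, bat, prof, seed = 51,
                                          artifact_rate = 0), 1)
    segs <- segment_recording(rec)
    mean(vapply(segs, function(s)
      mean(band_power(s)$theta[mont$regions == "frontal"]), 0))
  }
  p <- vapply(c(0.5, 1.0, 1.8), powers_for, 0)
  expect_length(segment_recording(
    generate_recording(cohort_spec(1, bat,
      list(a = workload_profile(1, 1, "moderate")), seed = 51), 1)), 31)
  expect_true(all(diff(p) > 0))
})

test_that("parietal alpha band power is monotone in the alpha gain", {
  bat <- mini_battery("a", 160)
  mont <- default_montage()
  powers_for <- function(gain) {
    prof <- list(a = workload_profile(1, gain, "moderate"))
    rec <- generate_recording(cohort_spec(1, bat, prof, seed = 52,
                                          artifact_rate = 0), 1)
    segs <- segment_recording(rec)
    mean(vapply(segs, function(s)
      mean(band_power(s)$alpha[mont$regions == "parietal"]), 0))
  }
  p <- vapply(c(0.5, 1.0, 1.8), powers_for, 0)
  expect_true(all(diff(p) > 0))
})

test_that("blink transients appear only when the artifact rate is positive", {
  bat <- mini_battery("a", 60)
  prof <- list(a = workload_profile(1, 1, "moderate"))
  quiet <- generate_recording(cohort_spec(1, bat, prof, seed = 53,
                                          artifact_rate = 0), 1)
  blinky <- generate_recording(cohort_spec(1, bat, prof, seed = 53,
                                           artifact_rate = 0.5), 1)
  fp <- grepl("^Fp", quiet$channels)
  expect_gt(max(abs(blinky$samples[fp, ])), max(abs(quiet$samples[fp, ])) + 50)
})

test_that("cohorts carry ground truth and accept a held-out block type", {
  bat <- mini_battery(c("easy", "hard"), 60)
  prof <- list(easy = workload_profile(0.5, 1.8, "low", grade = 1),
               hard = workload_profile(1.8, 0.5, "high", grade = 3),
               stop_signal = workload_profile(1.4, 0.7, "high", grade = 2.5))
  cohort <- generate_cohort(cohort_spec(2, bat, prof, seed = 54))
  expect_length(cohort, 2)
  expect_equal(cohort[[1]]$ground_truth$label, c("low", "high"))
  # held-out extra block appended to the battery
  bat2 <- rbind(bat, data.frame(task_id = "stop_signal", start_s = 120,
                                end_s = 180))
  cohort2 <- generate_cohort(cohort_spec(1, bat2, prof, seed = 54))
  expect_equal(nrow(cohort2[[1]]$recording$blocks), 3)
  gt <- cohort2[[1]]$ground_truth
  expect_equal(gt$grade[gt$task_id == "stop_signal"], 2.5)
  expect_true(gt$grade[gt$task_id == "stop_signal"] <
                gt$grade[gt$task_id == "hard"])
})

test_that("cohort specifications are validated", {
  bat <- mini_battery("a", 30)                 # too short for a baseline
  prof <- list(a = workload_profile(1, 1, "moderate"))
  expect_error(cohort_spec(1, bat, prof, seed = 1), ">= 60 s")
  expect_error(cohort_spec(0, mini_battery("a", 60), prof, seed = 1),
               "n_subjects")
  expect_error(cohort_spec(1, mini_battery("a", 60), list(), seed = 1),
               "profile")
  expect_error(cohort_spec(1, mini_battery("a", 60), prof), "seed")
  expect_error(workload_profile(-1, 1, "low"), "positive")
})

test_that("the archetypal labeled-map simulator honours rule and margin", {
  maps <- simulate_labeled_dfhm(200, margin = 1, seed = 55)
  labs <- vapply(maps, `[[`, "", "label")
  expect_true(all(labs %in% c("low", "moderate", "high")))
  # labels equal the rule applied to the realized maps (zero label noise)
  relabeled <- vapply(maps, auto_label, "")
  expect_identical(labs, relabeled)
  # class archetypes are separated by >= margin in region-mean space
  F_ <- vapply(maps, function(m) mean(m$values[m$region == "frontal"]), 0)
  expect_gt(mean(F_[labs == "high"]) - mean(F_[labs == "moderate"]), 1)
})
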