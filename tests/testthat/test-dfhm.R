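test_that("DFHM carries frontal theta and parietal alpha z-scores", {
  mont <- default_montage()
  set.seed(20)
  zt <- rnorm(25); za <- rnorm(25)
  z <- fake_zmap(zt, za, mont$labels)
  m <- make_dfhm(z, mont)
  frontal <- mont$regions == "frontal"
  expect_equal(unname(m$values[frontal]), zt[frontal])
  expect_equal(unname(m$values[!frontal]), za[!frontal])
  expect_length(m$values, 25)
  # specific electrode: Fz is frontal
  z2 <- fake_zmap(ifelse(mont$labels == "Fz", 1.7, 0),
                  ifelse(mont$labels == "Fz", -0.3, 0), mont$labels)
  expect_equal(unname(make_dfhm(z2, mont)$values["Fz"]), 1.7)
  # all-zero z-map -> all-zero DFHM
  expect_true(all(make_dfhm(fake_zmap(rep(0, 25), rep(0, 25),
                                      mont$labels), mont)$values == 0))
  # electrode set mismatch -> error
  expect_error(make_dfhm(fake_zmap(zt[-1], za[-1], mont$labels[-1]), mont),
               "different electrode")
})

test_that("a high-load archetype separates regions completely", {
  mont <- default_montage()
  frontal <- mont$regions == "frontal"
  z <- fake_zmap(rnorm(25, 2, 0.1), rnorm(25, -2, 0.1), mont$labels)
  m <- make_dfhm(z, mont)
  expect_gt(min(m$values[frontal]), max(m$values[!frontal]))
  expect_equal(auto_label(m), "high")
})

test_that("vectorization is a lossless round trip in montage order", {
  mont <- default_montage()
  set.seed(21)
  m <- vector_to_dfhm(rnorm(25), mont)
  v <- dfhm_to_vector(m)
  expect_length(v, 25)
  expect_equal(vector_to_dfhm(v, mont)$values, m$values)
  # two maps differing only at P3 produce vectors differing only there
  v2 <- v; v2[match("P3", mont$labels)] <- v2[match("P3", mont$labels)] + 1
  expect_equal(which(dfhm_to_vector(vector_to_dfhm(v2, mont)) != v),
               match("P3", mont$labels))
  expect_error(vector_to_dfhm(rnorm(10), mont), "montage size")
})

test_that("the labeling rule partitions region-mean space as specified", {
  mont <- default_montage()
  mk <- function(F, P) {
    vals <- ifelse(mont$regions == "frontal", F, P)
    vector_to_dfhm(vals, mont)
  }
  expect_equal(auto_label(mk(1.5, -1.5)), "high")
  expect_equal(auto_label(mk(-1.5, 1.5)), "low")
  expect_equal(auto_label(mk(0, 0)), "moderate")
  expect_equal(auto_label(mk(0.5, -0.5)), "high")    # thresholds inclusive
  expect_equal(auto_label(mk(0.49, -0.5)), "moderate")
  expect_equal(auto_label(mk(1.5, 1.5)), "moderate")
  expect_error(label_rule(tau_high = -1), "tau_high")
})

test_that("labeling is antisymmetric and total", {
  mont <- default_montage()
  set.seed(22)
  for (i in 1:50) {
    vals <- rnorm(25, 0, 1.5)
    m <- vector_to_dfhm(vals, mont)
    flip <- vector_to_dfhm(-vals, mont)
    lab <- auto_label(m)
    expect_true(lab %in% c("low", "moderate", "high"))
    if (lab == "high") expect_equal(auto_label(flip), "low")
    if (lab == "low") expect_equal(auto_label(flip), "high")
  }
})

test_that("training-map selection takes one first-minute segment per measurement", {
  bat <- default_battery()
  sel54 <- select_training_maps(stub_cohort(54, bat), bat)
  expect_equal(nrow(sel54), 540)              # 54 subjects x 10 measurements
  expect_false("AOSPAN" %in% sel54$task_id)
  expect_true(all(sel54$training))
  # selected segments start at their block start (first complete window)
  starts <- bat$start_s[match(sel54$task_id, bat$task_id)]
  expect_equal(sel54$start_s, starts)
  sel1 <- select_training_maps(stub_cohort(1, bat), bat)
  expect_equal(nrow(sel1), 10)
  expect_equal(nrow(select_training_maps(list(), bat)), 0)
  # subject missing one measurement: warned, remaining used
  cohort <- stub_cohort(1, bat)
  cohort$S01 <- Filter(function(s) s$task_id != "stroop", cohort$S01)
  expect_warning(selm <- select_training_maps(cohort, bat), "stroop")
  expect_equal(nrow(selm), 9)
})

test_that("labeled maps serialize to a flat table", {
  maps <- simulate_labeled_dfhm(12, seed = 30)
  tab <- dfhm_table(maps)
  expect_equal(nrow(tab), 12)
  expect_equal(ncol(tab), 4 + 25)
  expect_true(all(tab$label %in% c("low", "moderate", "high")))
  # table round-trips into the classifier input path
  d <- dfhm:::labeled_set_matrix(tab)
  expect_equal(dim(d$X), c(12, 25))
})
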