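test_that("BrainVision write/read round-trips samples and channel order", {
  set.seed(41)
  rec <- eeg_recording(matrix(rnorm(3 * 1000, sd = 20), 3), 500,
                       c("Fz", "Cz", "Pz"),
                       blocks = data.frame(task_id = "t", start_s = 0,
                                           end_s = 2))
  base <- file.path(withr::local_tempdir(), "rec")
  write_brainvision(rec, base)
  r1 <- read_recording(paste0(base, ".vhdr"))
  expect_equal(r1$rate, 500)
  expect_identical(r1$channels, rec$channels)
  # float32 storage: values agree to single precision...
  expect_equal(r1$samples, rec$samples, tolerance = 1e-6)
  # ...and a second round trip is bit-for-bit
  write_brainvision(r1, paste0(base, "_2"))
  r2 <- read_recording(paste0(base, "_2.vhdr"))
  expect_identical(r2$samples, r1$samples)
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(2 * 1000, sd = 30), 2), 500,
                       c("Fz", "Pz"))
  path <- file.path(withr::local_tempdir(), "rec.edf")
  write_edf(rec, path)
  r1 <- read_recording(path)
  expect_identical(r1$channels, rec$channels)
  expect_equal(r1$rate, 500)
  rng <- max(abs(rec$samples))
  expect_lt(max(abs(r1$samples - rec$samples)), rng / 32767 * 1.01)
})

test_that("degenerate files error without producing a partial recording", {
  d <- withr::local_tempdir()
  vhdr <- file.path(d, "empty.vhdr")
  file.create(vhdr)
  expect_error(read_recording(vhdr), "empty|malformed")
  # header pointing at a zero-length data file
  rec <- eeg_recording(matrix(0, 2, 500), 500, c("Fz", "Pz"))
  base <- file.path(d, "truncated")
  write_brainvision(rec, base)
  file.create(file.path(d, "truncated.eeg"))  # truncate to zero bytes
  expect_error(read_recording(paste0(base, ".vhdr")), "empty")
  expect_error(read_recording(file.path(d, "nope.vhdr")), "not found")
})

test_that("validate_montage canonicalizes order, drops extras, names missing", {
  mont <- default_montage()
  set.seed(1)
  shuffled <- sample(mont$labels)
  rec <- eeg_recording(matrix(rnorm(25 * 100), 25), 500, shuffled)
  v <- validate_montage(rec, mont)
  expect_identical(v$channels, mont$labels)
  expect_identical(v$samples[match("Pz", mont$labels), ],
                   rec$samples[match("Pz", shuffled), ])
  # idempotent
  expect_identical(validate_montage(v, mont)$samples, v$samples)
  # extra non-EEG channel is dropped with a warning
  rec2 <- eeg_recording(rbind(rec$samples, 0), 500, c(shuffled, "EOG"))
  expect_warning(v2 <- validate_montage(rec2, mont), "EOG")
  expect_identical(v2$channels, mont$labels)
  # missing electrode is an error naming the electrode
  rec3 <- eeg_recording(rec$samples[-match("Pz", shuffled), ], 500,
                        setdiff(shuffled, "Pz"))
  expect_error(validate_montage(rec3, mont), "Pz")
})

test_that("the default battery matches the canonical session layout", {
  bat <- default_battery()
  expect_equal(nrow(bat), 11)
  expect_equal(sum(bat$end_s - bat$start_s), 81 * 60)
  expect_true("AOSPAN" %in% bat$task_id)
  expect_equal(sum(grepl("rest", bat$task_id)), 2)
})

test_that("manifests round-trip and durations normalize to seconds", {
  d <- withr::local_tempdir()
  entries <- list(list(subject = "S01", path = "s01.vhdr",
                       blocks = default_battery()))
  p <- file.path(d, "manifest.yaml")
  write_manifest(entries, p)
  man <- read_manifest(p)
  expect_length(man, 1)
  expect_equal(nrow(man[[1]]$blocks), 11)
  expect_equal(sum(man[[1]]$blocks$end_s - man[[1]]$blocks$start_s), 4860)
  # minute-denominated blocks are converted
  writeLines(paste0(
    "- subject: S02\n  path: s02.vhdr\n  blocks:\n",
    "    - {task: rest, start_min: 0, end_min: 3}\n",
    "    - {task: 0-back, start_min: 3, end_min: 8}\n"),
    file.path(d, "m2.yaml"))
  m2 <- read_manifest(file.path(d, "m2.yaml"))
  expect_equal(m2[[1]]$blocks$end_s, c(180, 480))
  # empty manifest -> empty list
  writeLines("[]", file.path(d, "m0.yaml"))
  expect_length(read_manifest(file.path(d, "m0.yaml")), 0)
  # backwards block -> error
  writeLines(paste0(
    "- subject: S03\n  path: s03.vhdr\n  blocks:\n",
    "    - {task: rest, start_s: 100, end_s: 50}\n"),
    file.path(d, "m3.yaml"))
  expect_error(read_manifest(file.path(d, "m3.yaml")), "before")
  # overlapping blocks -> error
  writeLines(paste0(
    "- subject: S04\n  path: s04.vhdr\n  blocks:\n",
    "    - {task: a, start_s: 0, end_s: 100}\n",
    "    - {task: b, start_s: 50, end_s: 150}\n"),
    file.path(d, "m4.yaml"))
  expect_error(read_manifest(file.path(d, "m4.yaml")), "overlap")
})
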