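# Shared fixture builders. Everything is generated in code; no stored data.

# a segment carrying a pure sinusoid on every channel
sine_segment <- function(freq_hz, amplitude = 1, rate = 500, dur_s = 10,
                         channels = "Fz") {
  t <- (seq_len(rate * dur_s) - 1) / rate
  data <- matrix(rep(amplitude * sin(2 * pi * freq_hz * t),
                     each = length(channels)),
                 nrow = length(channels))
  dfhm:::new_eeg_segment(data, rate, 0, "task", "S01", channels)
}

# metadata-only segments (no samples) covering one block at 5 s cadence;
# enough for selection/bookkeeping operations
stub_segments <- function(task_id, start_s, end_s, window_s = 10,
                          step_s = 5, subject_id = "S01") {
  n <- dfhm::segment_count(end_s - start_s, window_s, step_s)
  lapply(seq_len(n), function(k)
    dfhm:::new_eeg_segment(NULL, 500, start_s + (k - 1) * step_s,
                           task_id, subject_id))
}

stub_cohort <- function(n_subjects, battery) {
  out <- lapply(seq_len(n_subjects), function(s) {
    unlist(lapply(seq_len(nrow(battery)), function(i)
      stub_segments(battery$task_id[i], battery$start_s[i],
                    battery$end_s[i],
                    subject_id = sprintf("S%02d", s))),
      recursive = FALSE)
  })
  names(out) <- sprintf("S%02d", seq_len(n_subjects))
  out
}

# hand-built band power vector (montage-ordered)
fake_power <- function(theta, alpha, channels, task_id = "task",
                       start_s = 0, subject_id = "S01") {
  structure(list(theta = theta, alpha = alpha, start_s = start_s,
                 task_id = task_id, subject_id = subject_id,
                 channels = channels),
            class = "band_power_vector")
}

# hand-built z-map
fake_zmap <- function(z_theta, z_alpha, channels) {
  structure(list(channels = channels, start_s = 0, task_id = "task",
                 subject_id = "S01", z_theta = z_theta, z_alpha = z_alpha),
            class = "zmap")
}

# small battery for fast pipeline runs
mini_battery <- function(tasks = c("easy", "hard"), dur_s = 60) {
  end <- cumsum(rep(dur_s, length(tasks)))
  data.frame(task_id = tasks, start_s = c(0, end[-length(end)]), end_s = end,
             stringsAsFactors = FALSE)
}
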