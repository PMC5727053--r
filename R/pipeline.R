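#' Preprocess a recording and cut it into segments
#'
#' The standard front end of the pipeline: montage validation and channel
#' canonicalization, 0.5-40 Hz linear-phase FIR bandpass, ICA artifact
#' removal under the given policy, average re-referencing, and 10 s / 5 s
#' segmentation restarted at each block boundary.
#'
#' @param rec an [eeg_recording()] with a block table.
#' @param montage the [dfhm_montage()].
#' @param filter_low,filter_high,filter_order bandpass settings.
#' @param artifact_policy see [remove_artifacts()]; `"none"` bypasses ICA.
#' @param window_s,step_s segmentation settings.
#' @return list with `recording` (cleaned) and `segments`.
#' @export
process_recording <- function(rec, montage = default_montage(),
                              filter_low = 0.5, filter_high = 40,
                              filter_order = 100,
                              artifact_policy = "blink_heuristic",
                              window_s = 10, step_s = 5) {
  rec <- validate_montage(rec, montage)
  rec <- bandpass_filter(rec, filter_low, filter_high, filter_order)
  rec <- remove_artifacts(rec, policy = artifact_policy)
  rec <- rereference_average(rec)
  list(recording = rec,
       segments = segment_recording(rec, window_s, step_s))
}

#' Fit the personalization baseline for one subject
#'
#' Convenience wrapper: selects the first-minute baseline segments of every
#' block, computes their band powers and fits [fit_baseline()].
#'
#' @param segments list of `eeg_segment` for the subject.
#' @param blocks the subject's block table.
#' @param bands band definitions.
#' @param subject_id subject identifier.
#' @param baseline_s,window_s see [collect_baseline()].
#' @return a `baseline_stats`.
#' @export
subject_baseline <- function(segments, blocks, bands = band_definitions(),
                             subject_id = NA_character_, baseline_s = 60,
                             window_s = 10) {
  bl <- collect_baseline(segments, blocks, baseline_s, window_s)
  if (length(bl) < 2L)
    stop("not enough baseline segments (need >= 2, got ", length(bl), ")")
  fit_baseline(lapply(bl, band_power, bands = bands), subject_id)
}

# flag the segments used as labeling/training material: the first complete
# window of each block (the deterministic training-map selection)
training_segment_flags <- function(segments, blocks) {
  vapply(segments, function(s) {
    i <- match(s$task_id, blocks$task_id)
    !is.na(i) && abs(s$start_s - blocks$start_s[i]) < 1e-9
  }, logical(1))
}

#' End-to-end workload index for one subject
#'
#' Full per-subject pipeline: preprocessing, baseline fit from the first
#' minutes, DFHM construction and classification by a frozen model pair,
#' and the 5 s index series. The first segment of each block (the
#' training-map selection) is flagged `training` so evaluation summaries
#' exclude it.
#'
#' @param rec the subject's [eeg_recording()] (with block table).
#' @param models a frozen `model_pair`.
#' @param montage the [dfhm_montage()].
#' @param bands band definitions.
#' @param ... passed to [process_recording()].
#' @return list with `series` (a `workload_index_series`), `baseline`, and
#'   `blocks`.
#' @export
subject_workload <- function(rec, models, montage = default_montage(),
                             bands = band_definitions(), ...) {
  pr <- process_recording(rec, montage, ...)
  base <- subject_baseline(pr$segments, rec$blocks, bands,
                           subject_id = rec$subject_id)
  flags <- training_segment_flags(pr$segments, rec$blocks)
  series <- workload_index(pr$segments, base, models, montage, bands,
                           training_flags = flags)
  list(series = series, baseline = base, blocks = rec$blocks)
}

#' Build a rule-labeled DFHM training set from a synthetic cohort
#'
#' Runs every subject of a cohort through the pipeline, z-scores all
#' segments against the subject baseline, builds DFHM and labels each map
#' with [auto_label()]. The result is the labeled material a frozen model
#' pair is trained on.
#'
#' @param cohort output of [generate_cohort()].
#' @param montage the [dfhm_montage()].
#' @param rule the [label_rule()].
#' @param bands band definitions.
#' @param ... passed to [process_recording()] (e.g. `artifact_policy`).
#' @return list of labeled `dfhm`.
#' @export
cohort_labeled_maps <- function(cohort, montage = default_montage(),
                                rule = label_rule(),
                                bands = band_definitions(), ...) {
  maps <- list()
  for (subj in cohort) {
    pr <- process_recording(subj$recording, montage, ...)
    base <- subject_baseline(pr$segments, subj$recording$blocks, bands,
                             subject_id = subj$recording$subject_id)
    for (s in pr$segments) {
      m <- make_dfhm(zscore_power(band_power(s, bands), base), montage)
      m$label <- auto_label(m, rule)
      maps[[length(maps) + 1L]] <- m
    }
  }
  maps
}

#' Balance a labeled DFHM set across classes
#'
#' Subsamples the majority classes so all three labels are equally
#' frequent, emulating the curated class coverage of a hand-labeled
#' training set. Detectors trained with a very small regularization weight
#' on a heavily imbalanced set otherwise collapse to the majority class.
#'
#' @param maps list of labeled `dfhm`.
#' @param seed RNG seed for the subsample.
#' @return the balanced subset, in stable order.
#' @export
balance_labeled_maps <- function(maps, seed = 1L) {
  labs <- vapply(maps, function(m) m$label %||% NA_character_, "")
  if (anyNA(labs)) stop("all maps must be labeled")
  set.seed(seed)
  nmin <- min(table(labs))
  keep <- sort(unlist(lapply(split(seq_along(maps), labs), sample, nmin)))
  maps[keep]
}

#' Evaluate the workload index over a cohort
#'
#' Applies a frozen model pair to every subject of a cohort (no
#' retraining), computes per-subject per-task portions, and summarises the
#' mean portion of high- and low-load segments per ground-truth demand
#' grade.
#'
#' @param cohort output of [generate_cohort()].
#' @param models a frozen `model_pair`.
#' @param montage the [dfhm_montage()].
#' @param bands band definitions.
#' @param ... passed to [process_recording()].
#' @return list with `series` (named per-subject list), `pct_high`,
#'   `pct_low` (subjects x tasks matrices), and `by_grade` (data frame of
#'   mean portions per demand grade, ordered low to high).
#' @export
evaluate_cohort <- function(cohort, models, montage = default_montage(),
                            bands = band_definitions(), ...) {
  series <- list()
  for (subj in cohort) {
    sw <- subject_workload(subj$recording, models, montage, bands, ...)
    series[[subj$recording$subject_id]] <- sw$series
  }
  ph <- cohort_table(series, "pct_high")
  pl <- cohort_table(series, "pct_low")
  gt <- cohort[[1]]$ground_truth
  grades <- sort(unique(gt$grade))
  by_grade <- do.call(rbind, lapply(grades, function(g) {
    tasks <- gt$task_id[gt$grade == g]
    data.frame(grade = g, tasks = paste(tasks, collapse = ","),
               mean_pct_high = mean(ph[, tasks, drop = FALSE], na.rm = TRUE),
               mean_pct_low = mean(pl[, tasks, drop = FALSE], na.rm = TRUE))
  }))
  list(series = series, pct_high = ph, pct_low = pl, by_grade = by_grade)
}
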