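#' Build a Dual Frequency Head Map
#'
#' Fuses a z-map into one head map: frontal electrodes carry the theta-band
#' z-score, parietal electrodes carry the alpha-band z-score. Electrode
#' (spatial) order follows the montage; no interpolation is performed — the
#' map is an electrode-indexed vector.
#'
#' @param z a `zmap` (from [zscore_power()]).
#' @param montage a [dfhm_montage()] covering the same electrodes.
#' @return object of class `dfhm`: `values` (named numeric, montage order),
#'   `region` (named character), optional `label`, and segment metadata.
#' @export
make_dfhm <- function(z, montage = default_montage()) {
  stopifnot(inherits(z, "zmap"), inherits(montage, "dfhm_montage"))
  if (!setequal(z$channels, montage$labels))
    stop("z-map and montage cover different electrode sets")
  idx <- match(montage$labels, z$channels)
  vals <- ifelse(montage$regions == "frontal",
                 z$z_theta[idx], z$z_alpha[idx])
  names(vals) <- montage$labels
  structure(list(values = vals, region = montage$regions, label = NULL,
                 start_s = z$start_s, task_id = z$task_id,
                 subject_id = z$subject_id),
            class = "dfhm")
}

#' @export
print.dfhm <- function(x, ...) {
  cat(sprintf("<dfhm> %d electrodes  F=%.2f P=%.2f  label=%s\n",
              length(x$values), mean(x$values[x$region == "frontal"]),
              mean(x$values[x$region == "parietal"]),
              x$label %||% "<none>"))
  invisible(x)
}

#' Flatten a DFHM to a feature vector (and back)
#'
#' The classifier consumes maps as plain numeric vectors in fixed montage
#' order; `vector_to_dfhm()` is the exact inverse given the montage.
#'
#' @param m a `dfhm`.
#' @return numeric vector of length equal to the montage size.
#' @export
dfhm_to_vector <- function(m) {
  stopifnot(inherits(m, "dfhm"))
  unname(m$values)
}

#' @rdname dfhm_to_vector
#' @param x numeric vector in montage order.
#' @param montage the [dfhm_montage()] the vector was built against.
#' @export
vector_to_dfhm <- function(x, montage = default_montage()) {
  if (length(x) != length(montage$labels))
    stop("vector length ", length(x), " does not match montage size ",
         length(montage$labels))
  vals <- as.numeric(x)
  names(vals) <- montage$labels
  structure(list(values = vals, region = montage$regions, label = NULL,
                 start_s = NA_real_, task_id = NA_character_,
                 subject_id = NA_character_),
            class = "dfhm")
}

#' Labeling rule for DFHM
#'
#' Codifies the visual labeling of head maps with a symmetric z-threshold on
#' the two region means: pronounced frontal theta elevation together with
#' pronounced parietal alpha suppression reads as high load, the mirror
#' image as low load, everything else as moderate. The default threshold of
#' 0.5 z-units is this package's choice of what counts as "pronounced" and
#' is deliberately configurable.
#'
#' @param tau_high positive threshold for a "high" region mean.
#' @param tau_low negative threshold for a "low" region mean (default
#'   `-tau_high`).
#' @return object of class `label_rule`.
#' @export
label_rule <- function(tau_high = 0.5, tau_low = -tau_high) {
  if (!(tau_high > 0) || !(tau_low < 0))
    stop("tau_high must be > 0 and tau_low < 0")
  structure(list(tau_high = tau_high, tau_low = tau_low),
            class = "label_rule")
}

#' Auto-label a DFHM
#'
#' With `F` the mean frontal value and `P` the mean parietal value:
#' `F >= tau_high` and `P <= tau_low` gives `"high"`; `F <= tau_low` and
#' `P >= tau_high` gives `"low"`; everything else is `"moderate"`. Exactly
#' one label is always produced.
#'
#' @param m a `dfhm`.
#' @param rule a [label_rule()].
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
auto_label <- function(m, rule = label_rule()) {
  stopifnot(inherits(m, "dfhm"))
  F_ <- mean(m$values[m$region == "frontal"])
  P_ <- mean(m$values[m$region == "parietal"])
  if (F_ >= rule$tau_high && P_ <= rule$tau_low) "high"
  else if (F_ <= rule$tau_low && P_ >= rule$tau_high) "low"
  else "moderate"
}

#' Select the training-map segments (one first-minute segment per measurement)
#'
#' Reproduces the training-set construction: for every subject and every
#' eligible measurement (all battery blocks except the AOSPAN-type task),
#' exactly one segment of the block's first minute — the first complete
#' window of the block — is selected for labeling and classifier training.
#' Selected segments are flagged so downstream evaluation can exclude them
#' from classifier testing.
#'
#' @param cohort_segments named list: subject id -> list of `eeg_segment`.
#' @param battery block table defining the measurements (`task_id` column).
#' @param exclude_task task id(s) excluded from labeling (default
#'   `"AOSPAN"`).
#' @return data frame with one row per selected segment: `subject_id`,
#'   `task_id`, `start_s`, `segment_index` (position in the subject's
#'   segment list), and `training = TRUE`. Subjects missing a measurement
#'   contribute their available ones, with a warning.
#' @export
select_training_maps <- function(cohort_segments, battery,
                                 exclude_task = "AOSPAN") {
  eligible <- setdiff(unique(battery$task_id), exclude_task)
  rows <- list()
  for (subj in names(cohort_segments)) {
    segs <- cohort_segments[[subj]]
    task <- vapply(segs, `[[`, "", "task_id")
    start <- vapply(segs, `[[`, 0, "start_s")
    for (tk in eligible) {
      in_task <- which(task == tk)
      if (!length(in_task)) next
      first <- in_task[which.min(start[in_task])]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, task_id = tk, start_s = start[first],
        segment_index = first, training = TRUE, stringsAsFactors = FALSE)
    }
    got <- unique(task)
    miss <- setdiff(eligible, got)
    if (length(miss))
      warning("subject ", subj, " is missing measurement(s): ",
              paste(miss, collapse = ", "))
  }
  if (!length(rows))
    return(data.frame(subject_id = character(), task_id = character(),
                      start_s = numeric(), segment_index = integer(),
                      training = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Tabulate labeled DFHM
#'
#' Serializes a list of labeled maps to a flat table (one row per map:
#' subject, task, segment start, one column per electrode, label), the
#' interchange format for labeled training sets.
#'
#' @param maps list of `dfhm` with labels set.
#' @return data frame.
#' @export
dfhm_table <- function(maps) {
  stopifnot(length(maps) > 0)
  vals <- do.call(rbind, lapply(maps, dfhm_to_vector))
  colnames(vals) <- names(maps[[1]]$values)
  meta <- data.frame(
    subject_id = vapply(maps, function(m) m$subject_id %||% NA_character_, ""),
    task_id = vapply(maps, function(m) m$task_id %||% NA_character_, ""),
    start_s = vapply(maps, function(m) m$start_s %||% NA_real_, 0),
    label = vapply(maps, function(m) m$label %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(vals))
}
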