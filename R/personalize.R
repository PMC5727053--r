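#' Select baseline segments (first minute of each block)
#'
#' The personalization baseline is built from the segments whose window lies
#' entirely within the first `baseline_s` seconds of each block. At the
#' default 10 s window / 5 s step and `baseline_s = 60` this yields 11
#' segments per block. All blocks contribute by default, rest measurements
#' included, so the baseline spans the subject's range of oscillatory
#' states; set `include_tasks` to restrict.
#'
#' @param segments list of `eeg_segment` (from [segment_recording()]).
#' @param blocks block table (`task_id`, `start_s`, `end_s`).
#' @param baseline_s length of the per-block baseline window (default 60).
#' @param window_s segment window length in seconds.
#' @param include_tasks optional character vector of task ids to keep.
#' @return the baseline subset of `segments`. Blocks shorter than the
#'   segment window are skipped with a warning.
#' @export
collect_baseline <- function(segments, blocks, baseline_s = 60,
                             window_s = 10, include_tasks = NULL) {
  if (length(segments) == 0L || NROW(blocks) == 0L) return(list())
  short <- blocks$end_s - blocks$start_s < window_s
  if (any(short))
    warning("skipping block(s) shorter than the segment window: ",
            paste(blocks$task_id[short], collapse = ", "))
  blocks <- blocks[!short, , drop = FALSE]
  if (!is.null(include_tasks))
    blocks <- blocks[blocks$task_id %in% include_tasks, , drop = FALSE]
  keep <- vapply(segments, function(s) {
    i <- match(s$task_id, blocks$task_id)
    !is.na(i) &&
      s$start_s >= blocks$start_s[i] - 1e-9 &&
      s$start_s + window_s <= blocks$start_s[i] + baseline_s + 1e-9
  }, logical(1))
  segments[keep]
}

#' Fit per-subject baseline statistics
#'
#' Computes, per electrode and band, the mean and sample standard deviation
#' (n-1 denominator) of band power over the contributing baseline segments —
#' the only subject-specific parameters of the workload index.
#'
#' @param powers list of `band_power_vector` (from [band_power()]) for the
#'   baseline segments of one subject.
#' @param subject_id subject identifier.
#' @return object of class `baseline_stats`: per-band `mean` and `sd`
#'   matrices are flattened to named lists (`mean_theta`, `sd_theta`,
#'   `mean_alpha`, `sd_alpha`, each one value per electrode), plus
#'   `channels`, `subject_id` and `n_segments`.
#' @export
fit_baseline <- function(powers, subject_id = NA_character_) {
  if (length(powers) < 2L)
    stop("baseline needs at least 2 contributing segments, got ",
         length(powers))
  channels <- powers[[1]]$channels
  bands <- setdiff(names(powers[[1]]),
                   c("start_s", "task_id", "subject_id", "channels"))
  out <- list(subject_id = subject_id, channels = channels,
              n_segments = length(powers))
  for (b in bands) {
    mat <- do.call(rbind, lapply(powers, `[[`, b))   # segments x electrodes
    mu <- colMeans(mat)
    sdv <- apply(mat, 2, stats::sd)
    if (any(sdv <= 0)) {
      bad <- channels[sdv <= 0] %||% which(sdv <= 0)
      stop("degenerate baseline: zero ", b, " power variance at electrode(s) ",
           paste(bad, collapse = ", "))
    }
    out[[paste0("mean_", b)]] <- mu
    out[[paste0("sd_", b)]] <- sdv
  }
  structure(out, class = "baseline_stats")
}

#' Z-score a band power vector against a subject baseline
#'
#' `z = (power - mean) / sd` per electrode and band, removing
#' inter-individual differences in absolute band power.
#'
#' @param power a `band_power_vector`.
#' @param base a `baseline_stats` covering the same electrodes.
#' @return object of class `zmap` with per-band z vectors (`z_theta`,
#'   `z_alpha`), `channels`, and segment metadata.
#' @export
zscore_power <- function(power, base) {
  stopifnot(inherits(power, "band_power_vector"),
            inherits(base, "baseline_stats"))
  if (!identical(as.character(power$channels), as.character(base$channels)))
    stop("baseline and power cover different electrode sets")
  bands <- setdiff(names(power),
                   c("start_s", "task_id", "subject_id", "channels"))
  out <- list(channels = power$channels, start_s = power$start_s,
              task_id = power$task_id, subject_id = power$subject_id)
  for (b in bands) {
    mu <- base[[paste0("mean_", b)]]
    sdv <- base[[paste0("sd_", b)]]
    if (is.null(mu))
      stop("baseline has no statistics for band ", b)
    out[[paste0("z_", b)]] <- (power[[b]] - mu) / sdv
  }
  structure(out, class = "zmap")
}

#' Save / load baseline statistics as a JSON sidecar
#'
#' The sidecar carries everything classification needs about a subject, so
#' the index can run on new recordings without re-reading the baseline EEG.
#'
#' @param base a `baseline_stats`.
#' @param path JSON file path.
#' @return `path` (write) or a `baseline_stats` (read).
#' @export
write_baseline <- function(base, path) {
  stopifnot(inherits(base, "baseline_stats"))
  jsonlite::write_json(unclass(base), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(obj, class = "baseline_stats")
}
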