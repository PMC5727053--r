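#' EEG recording container
#'
#' An `eeg_recording` holds a continuous multichannel EEG signal in
#' microvolts together with its acquisition metadata and the block structure
#' (which task was running when). The sample matrix is channels x time, one
#' row per electrode, in the channel order of the header (or, after
#' [validate_montage()], in canonical montage order).
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of 10-20 electrode labels, one per row
#'   of `samples`, all unique.
#' @param reference reference annotation: an electrode label (e.g. `"Cz"`)
#'   or `"average"`.
#' @param blocks data frame with columns `task_id`, `start_s`, `end_s`
#'   describing non-overlapping task blocks within the recording, or `NULL`.
#' @param subject_id optional subject identifier.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channels, reference = "Cz",
                          blocks = NULL, subject_id = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  channels <- as.character(channels)
  if (nrow(samples) != length(channels))
    stop("samples has ", nrow(samples), " rows but ", length(channels),
         " channel labels were given")
  if (anyDuplicated(channels))
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  dur <- ncol(samples) / rate
  blocks <- validate_blocks(blocks, dur)
  structure(
    list(samples = samples, rate = rate, channels = channels,
         reference = reference, blocks = blocks, subject_id = subject_id),
    class = "eeg_recording")
}

# Blocks must be a data.frame(task_id, start_s, end_s), non-overlapping,
# inside [0, duration]. Returns a normalized copy (or an empty frame).
validate_blocks <- function(blocks, duration_s = Inf) {
  if (is.null(blocks) || NROW(blocks) == 0L)
    return(data.frame(task_id = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE))
  blocks <- as.data.frame(blocks)
  need <- c("task_id", "start_s", "end_s")
  if (!all(need %in% names(blocks)))
    stop("blocks must have columns task_id, start_s, end_s")
  blocks <- blocks[need]
  blocks$task_id <- as.character(blocks$task_id)
  if (any(blocks$end_s <= blocks$start_s))
    stop("block end before (or at) start for task(s): ",
         paste(blocks$task_id[blocks$end_s <= blocks$start_s], collapse = ", "))
  if (any(blocks$start_s < 0) || any(blocks$end_s > duration_s + 1e-9))
    stop("blocks must lie within the recording duration (",
         signif(duration_s, 6), " s)")
  o <- order(blocks$start_s)
  blocks <- blocks[o, , drop = FALSE]
  if (nrow(blocks) > 1L &&
      any(blocks$start_s[-1L] < blocks$end_s[-nrow(blocks)] - 1e-9))
    stop("blocks overlap")
  rownames(blocks) <- NULL
  blocks
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("  reference:", x$reference, " subject:", x$subject_id, "\n")
  if (nrow(x$blocks))
    cat("  blocks:", paste(sprintf("%s[%g-%gs]", x$blocks$task_id,
                                   x$blocks$start_s, x$blocks$end_s),
                           collapse = " "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate
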