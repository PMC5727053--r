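#' Electrode montage with frontal/parietal region assignment
#'
#' The DFHM method needs every electrode assigned to exactly one of two
#' regions: "frontal" electrodes carry theta-band z-scores, "parietal"
#' electrodes carry alpha-band z-scores. A montage is the ordered list of
#' electrode labels plus that region mapping.
#'
#' @param labels character vector of unique 10-20 electrode labels.
#' @param regions character vector (same length) with values `"frontal"` or
#'   `"parietal"`, or a named vector mapping label -> region.
#'
#' @return An object of class `dfhm_montage`: a list with `labels` and
#'   `regions` (named character vector).
#' @export
dfhm_montage <- function(labels, regions) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  if (!is.null(names(regions))) {
    if (!setequal(names(regions), labels))
      stop("named regions must cover exactly the montage labels")
    regions <- regions[labels]
  }
  regions <- as.character(regions)
  if (length(regions) != length(labels))
    stop("labels and regions must have the same length")
  if (!all(regions %in% c("frontal", "parietal")))
    stop("regions must be 'frontal' or 'parietal'")
  if (!all(c("frontal", "parietal") %in% regions))
    stop("both regions must be non-empty")
  names(regions) <- labels
  structure(list(labels = labels, regions = regions), class = "dfhm_montage")
}

#' Default 25-channel montage
#'
#' A reconstructed, configurable 25-electrode 10-20 layout. The fronto-polar,
#' frontal and fronto-central rows form the "frontal" region; the central,
#' centro-parietal, parietal and occipital rows form the "parietal" region
#' (the central row is folded into the parietal group so that every
#' electrode belongs to exactly one region). Users whose caps differ should
#' build their own [dfhm_montage()].
#'
#' @return A `dfhm_montage` with 25 labels (11 frontal, 14 parietal).
#' @export
default_montage <- function() {
  frontal <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC1", "FC2", "FC6")
  parietal <- c("T7", "C3", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8", "Oz")
  dfhm_montage(c(frontal, parietal),
               c(rep("frontal", length(frontal)),
                 rep("parietal", length(parietal))))
}

#' @export
print.dfhm_montage <- function(x, ...) {
  cat(sprintf("<dfhm_montage> %d electrodes (%d frontal, %d parietal)\n",
              length(x$labels), sum(x$regions == "frontal"),
              sum(x$regions == "parietal")))
  invisible(x)
}

#' Check and canonicalize a recording against a montage
#'
#' Reorders the recording's channels to montage order. Channels present in
#' the recording but absent from the montage (e.g. EOG/EMG auxiliaries) are
#' dropped with a warning. A montage electrode missing from the recording is
#' an error.
#'
#' @param rec an [eeg_recording()].
#' @param montage a [dfhm_montage()].
#' @return The recording with channels in canonical montage order.
#' @export
validate_montage <- function(rec, montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "dfhm_montage"))
  missing <- setdiff(montage$labels, rec$channels)
  if (length(missing))
    stop("recording is missing montage channel(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(rec$channels, montage$labels)
  if (length(extra))
    warning("dropping non-montage channel(s): ", paste(extra, collapse = ", "))
  idx <- match(montage$labels, rec$channels)
  rec$samples <- rec$samples[idx, , drop = FALSE]
  rec$channels <- montage$labels
  rec
}
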