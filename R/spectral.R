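#' Frequency band definitions
#'
#' Bands are half-open intervals `[low_hz, high_hz)`, so the 8 Hz bin
#' belongs to alpha and not to theta. Defaults are the workload-relevant
#' bands: theta 4-8 Hz, alpha 8-12 Hz.
#'
#' @param theta,alpha length-2 numeric `c(low_hz, high_hz)`.
#' @return named list of band definitions.
#' @export
band_definitions <- function(theta = c(4, 8), alpha = c(8, 12)) {
  bands <- list(theta = theta, alpha = alpha)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0)
      stop("band ", nm, " must be c(low_hz, high_hz) with 0 <= low < high")
  }
  bands
}

#' Per-electrode band power of a segment
#'
#' One Hamming-tapered FFT over the full segment per electrode (no Welch
#' averaging); band power is the sum of periodogram power over the FFT bins
#' whose frequency lies in `[low_hz, high_hz)`. The taper normalization is
#' chosen so that a unit-amplitude sinusoid inside a band contributes
#' approximately `0.5` (its mean-square power) in microvolt-squared units.
#'
#' @param seg an `eeg_segment` (from [segment_recording()]).
#' @param bands band list from [band_definitions()].
#' @return object of class `band_power_vector`: a list with one numeric
#'   vector per band (one value per electrode, montage order), plus segment
#'   metadata (`start_s`, `task_id`, `subject_id`, `channels`).
#' @export
band_power <- function(seg, bands = band_definitions()) {
  stopifnot(inherits(seg, "eeg_segment"), !is.null(seg$data))
  n <- ncol(seg$data)
  nyq <- seg$rate / 2
  for (nm in names(bands)) {
    if (bands[[nm]][2] > nyq)
      stop("band ", nm, " exceeds the Nyquist frequency (", nyq, " Hz)")
    if (n / seg$rate < 2 / bands[[nm]][1])
      stop("segment too short to resolve band ", nm)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hamming taper
  norm <- 2 / (n * sum(w^2))
  freqs <- (seq_len(n) - 1) * seg$rate / n
  X <- stats::mvfft(t(seg$data * rep(w, each = nrow(seg$data))))
  P <- Mod(X)^2 * norm                       # one-sided periodogram, n x ch
  powers <- lapply(bands, function(b) {
    sel <- freqs >= b[1] & freqs < b[2] & freqs > 0 & freqs <= nyq
    colSums(P[sel, , drop = FALSE])
  })
  structure(c(powers,
              list(start_s = seg$start_s, task_id = seg$task_id,
                   subject_id = seg$subject_id, channels = seg$channels)),
            class = "band_power_vector")
}
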