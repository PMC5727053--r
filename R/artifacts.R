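#' Remove artifact components by ICA
#'
#' Decomposes the (filtered) recording with Infomax ICA, flags artifact
#' components with a pluggable policy, and projects the remaining components
#' back onto the scalp channels. The default policy targets ocular
#' artifacts: a component is rejected when its scalp topography is dominated
#' by the fronto-polar electrodes and its source power is concentrated below
#' the theta band, or when its source kurtosis is extreme (spiky transients).
#'
#' The decomposition is deterministic: Infomax is run from the identity
#' rotation (no random restart).
#'
#' @param rec an [eeg_recording()] with at least 2 channels, already
#'   bandpass filtered.
#' @param policy `"blink_heuristic"` (default), `"none"` (bypass: the
#'   recording is returned untouched), or a function
#'   `f(source, mixing_col, rate, channels)` returning `TRUE` for artifact
#'   components.
#' @param max_components number of ICA components (default: channel count).
#' @param maxit,tol Infomax iteration cap and convergence tolerance;
#'   non-convergence is an error, never silently ignored.
#' @return the cleaned recording, with attribute `"rejected_components"`
#'   (integer indices of removed components).
#' @export
remove_artifacts <- function(rec, policy = "blink_heuristic",
                             max_components = NULL, maxit = 200, tol = 1e-6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (identical(policy, "none")) {
    attr(rec, "rejected_components") <- integer()
    return(rec)
  }
  if (nrow(rec$samples) < 2L)
    stop("ICA artifact removal needs at least 2 channels")
  nc <- max_components %||% nrow(rec$samples)
  X <- t(rec$samples)                       # time x channels
  dec <- ica::icaimax(X, nc = nc, center = TRUE, maxit = maxit, tol = tol)
  if (is.null(dec$converged)) {
    # ica reports iterations; treat hitting the cap as non-convergence
    if (!is.null(dec$iter) && dec$iter >= maxit)
      stop("Infomax ICA did not converge within ", maxit,
           " iterations (final tol status unavailable); ",
           "raise maxit or relax tol")
  }
  pol <- if (is.function(policy)) policy
         else switch(policy,
                     blink_heuristic = blink_policy,
                     stop("unknown artifact policy: ", policy))
  centers <- colMeans(X)
  reject <- which(vapply(seq_len(nc), function(k) {
    isTRUE(pol(dec$S[, k], dec$M[, k], rec$rate, rec$channels))
  }, logical(1)))
  if (length(reject)) {
    keep <- setdiff(seq_len(nc), reject)
    clean <- dec$S[, keep, drop = FALSE] %*% t(dec$M[, keep, drop = FALSE])
    rec$samples <- t(sweep(clean, 2, centers, `+`))
  }
  attr(rec, "rejected_components") <- reject
  rec
}

# Default ocular-artifact policy. A blink component mixes almost entirely
# into Fp1/Fp2 and its source energy sits below 4 Hz; muscle/motion spikes
# show extreme kurtosis.
blink_policy <- function(source, mixing_col, rate, channels,
                         fp_frac = 0.35, lf_frac = 0.60, kurt_max = 15) {
  w <- abs(mixing_col)
  fp <- grepl("^(Fp1|Fp2|Fpz)$", channels)
  fp_dominance <- if (any(fp)) sum(w[fp]) / sum(w) else 0
  n <- length(source)
  spec <- Mod(stats::fft(source - mean(source)))^2
  freqs <- (seq_len(n) - 1) * rate / n
  pos <- freqs > 0 & freqs <= rate / 2
  low <- sum(spec[pos & freqs < 4]) / max(sum(spec[pos]), .Machine$double.eps)
  k <- mean((source - mean(source))^4) / stats::var(source)^2
  (fp_dominance > fp_frac && low > lf_frac) || k > kurt_max
}
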