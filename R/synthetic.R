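#' Workload profile of a task block
#'
#' A profile scales the two spectral signatures of mental workload in the
#' generator: the frontal theta oscillation amplitude rises with load, the
#' parietal alpha oscillation amplitude falls with it.
#'
#' @param theta_gain_frontal amplitude multiplier (> 0) of the frontal
#'   theta oscillation.
#' @param alpha_gain_parietal amplitude multiplier (> 0) of the parietal
#'   alpha oscillation.
#' @param label ground-truth condition (`"low"`, `"moderate"`, `"high"`).
#' @param grade numeric position on the low-to-high demand axis (used to
#'   order conditions in evaluations; defaults to the theta gain).
#' @return object of class `workload_profile`.
#' @export
workload_profile <- function(theta_gain_frontal, alpha_gain_parietal,
                             label = c("low", "moderate", "high"),
                             grade = theta_gain_frontal) {
  label <- match.arg(label)
  if (theta_gain_frontal <= 0 || alpha_gain_parietal <= 0)
    stop("gains must be positive")
  structure(list(theta_gain_frontal = theta_gain_frontal,
                 alpha_gain_parietal = alpha_gain_parietal,
                 label = label, grade = grade),
            class = "workload_profile")
}

#' Default task -> profile mapping
#'
#' Graded conditions reflecting the canonical demand ordering of the
#' battery: rests and the easy tasks (0-back, switch-PAR, switch-NUM) are
#' low load; the working-memory and inhibition tasks are moderate; AOSPAN
#' is high. A `stop_signal` profile between moderate and high is included
#' for held-out-task evaluations.
#'
#' @return named list of [workload_profile()]s, indexed by task id.
#' @export
default_profiles <- function() {
  low <- function() workload_profile(0.5, 1.8, "low", grade = 1)
  mod <- function() workload_profile(1.0, 1.0, "moderate", grade = 2)
  list(
    rest_start = low(), rest_end = low(), `0-back` = low(),
    `switch-PAR` = low(), `switch-NUM` = low(),
    `2-back` = mod(), sternberg = mod(), ser_sternberg = mod(),
    stroop = mod(), `switch-XXX` = mod(),
    stop_signal = workload_profile(1.4, 0.7, "high", grade = 2.5),
    AOSPAN = workload_profile(1.8, 0.5, "high", grade = 3))
}

#' Synthetic cohort specification
#'
#' Defines a cohort of simulated subjects: the task battery (block layout),
#' the per-task workload profiles, the 1/f background noise, per-subject
#' gain variability, blink artifact rate, and the master seed. Everything
#' downstream is deterministic given the spec.
#'
#' Default amplitudes are calibrated so that the band-power
#' signal-to-background ratio of the workload signature is about 2 under
#' the moderate profile: pink-noise rms 10 uV puts roughly 11 uV^2 in the
#' theta band and 6.5 uV^2 in the alpha band, and the default oscillation
#' rms amplitudes (6.6 uV theta, 5.1 uV alpha at gain 1) double those.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param battery block table, e.g. [default_battery()]; all block
#'   durations must be >= 60 s so baselines can be extracted.
#' @param profiles named list of [workload_profile()] covering every task
#'   in the battery.
#' @param seed master RNG seed (mandatory; per-subject seeds are derived).
#' @param rate sampling rate in Hz.
#' @param noise list with `exponent` (1/f slope, default 1) and `rms`
#'   (background rms amplitude in uV, default 10).
#' @param osc_rms_theta,osc_rms_alpha oscillation rms amplitude in uV at
#'   gain 1.
#' @param subject_jitter_sd log-normal sd of the per-subject gain jitter.
#' @param artifact_rate blink events per second at fronto-polar channels
#'   (0 disables blinks).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, battery = default_battery(),
                        profiles = default_profiles(), seed,
                        rate = 500,
                        noise = list(exponent = 1, rms = 10),
                        osc_rms_theta = 6.6, osc_rms_alpha = 5.1,
                        subject_jitter_sd = 0.08,
                        artifact_rate = 0.1) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  battery <- validate_blocks(battery)
  if (any(battery$end_s - battery$start_s < 60 - 1e-9))
    stop("all battery blocks must last >= 60 s (baseline requirement)")
  missing_prof <- setdiff(battery$task_id, names(profiles))
  if (length(missing_prof))
    stop("no workload profile for task(s): ",
         paste(missing_prof, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects), battery = battery,
                 profiles = profiles, seed = as.integer(seed), rate = rate,
                 noise = noise, osc_rms_theta = osc_rms_theta,
                 osc_rms_alpha = osc_rms_alpha,
                 subject_jitter_sd = subject_jitter_sd,
                 artifact_rate = artifact_rate),
            class = "cohort_spec")
}

# 1/f^exponent background noise, fixed rms, via spectral shaping of white
# noise.
pink_noise <- function(n, rate, exponent = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  k <- seq_len(n) - 1
  f2 <- pmin(k, n - k) * rate / n                  # two-sided frequency axis
  f2[1] <- Inf                                     # kill DC
  shaped <- X / f2^(exponent / 2)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Smooth positive amplitude envelope with unit mean-square, built from
# 2-second-spaced Gaussian knots; gives the band power its
# segment-to-segment variance.
burst_envelope <- function(n, rate, depth = 0.5, knot_s = 2) {
  nk <- max(4L, ceiling(n / rate / knot_s) + 2L)
  knots <- stats::rnorm(nk)
  env <- stats::approx(seq(0, by = knot_s, length.out = nk), knots,
                       xout = (seq_len(n) - 1) / rate, rule = 2)$y
  env <- 1 + depth * env / stats::sd(env)
  env <- pmax(env, 0.15)
  env / sqrt(mean(env^2))
}

#' Generate one synthetic EEG recording
#'
#' Builds a 25-channel recording for one subject of a [cohort_spec()]:
#' per-channel 1/f background, a shared frontal theta oscillation
#' (random frequency in 4-8 Hz per block, burst-modulated amplitude scaled
#' by the block profile's theta gain), a shared parietal alpha oscillation
#' (8-12 Hz, scaled by the alpha gain), and optional blink transients at
#' the fronto-polar channels. Per-subject gain jitter is drawn once per
#' subject. Fully deterministic given (spec, subject index).
#'
#' @param spec a [cohort_spec()].
#' @param subject integer subject index in `1:n_subjects`.
#' @param montage the montage to synthesize (default [default_montage()]).
#' @return an [eeg_recording()] with the battery's block table attached.
#' @export
generate_recording <- function(spec, subject, montage = default_montage()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (subject < 1 || subject > spec$n_subjects)
    stop("subject index out of range")
  set.seed((spec$seed + 1000003L * as.integer(subject)) %% 2147483647L)
  labels <- montage$labels
  nchan <- length(labels)
  frontal <- montage$regions == "frontal"
  parietal <- !frontal
  # subject-level parameters, drawn once
  theta_jit <- exp(stats::rnorm(1, 0, spec$subject_jitter_sd))
  alpha_jit <- exp(stats::rnorm(1, 0, spec$subject_jitter_sd))
  chan_gain <- stats::runif(nchan, 0.85, 1.15)
  blink_w <- ifelse(grepl("^Fp", labels), 1,
                    ifelse(grepl("^F", labels), 0.3, 0.05))
  blocks <- spec$battery
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    dur <- blocks$end_s[i] - blocks$start_s[i]
    n <- round(dur * spec$rate)
    prof <- spec$profiles[[blocks$task_id[i]]]
    tt <- (seq_len(n) - 1) / spec$rate
    block <- matrix(0, nchan, n)
    for (ch in seq_len(nchan))
      block[ch, ] <- spec$noise$rms *
        pink_noise(n, spec$rate, spec$noise$exponent)
    f_theta <- stats::runif(1, 4.2, 7.8)
    f_alpha <- stats::runif(1, 8.2, 11.8)
    th <- spec$osc_rms_theta * sqrt(2) * prof$theta_gain_frontal * theta_jit *
      burst_envelope(n, spec$rate) * sin(2 * pi * f_theta * tt +
                                         stats::runif(1, 0, 2 * pi))
    al <- spec$osc_rms_alpha * sqrt(2) * prof$alpha_gain_parietal * alpha_jit *
      burst_envelope(n, spec$rate) * sin(2 * pi * f_alpha * tt +
                                         stats::runif(1, 0, 2 * pi))
    block[frontal, ] <- block[frontal, ] +
      outer(chan_gain[frontal], th)
    block[parietal, ] <- block[parietal, ] +
      outer(chan_gain[parietal], al)
    if (spec$artifact_rate > 0) {
      n_blinks <- stats::rpois(1, spec$artifact_rate * dur)
      if (n_blinks > 0) {
        blen <- round(0.4 * spec$rate)
        shape <- 120 * sin(pi * seq_len(blen) / blen)^2
        starts <- sort(sample.int(max(n - blen, 1), n_blinks, replace = TRUE))
        for (s0 in starts) {
          idx <- s0:min(s0 + blen - 1, n)
          block[, idx] <- block[, idx] +
            outer(blink_w, shape[seq_along(idx)])
        }
      }
    }
    out[[i]] <- block
  }
  eeg_recording(do.call(cbind, out), spec$rate, labels, reference = "Cz",
                blocks = blocks, subject_id = sprintf("S%02d", subject))
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param montage montage to synthesize.
#' @return list with one element per subject: `recording` (an
#'   [eeg_recording()]) and `ground_truth` (data frame of per-block profile
#'   labels, grades and gains).
#' @export
generate_cohort <- function(spec, montage = default_montage()) {
  stopifnot(inherits(spec, "cohort_spec"))
  gt <- do.call(rbind, lapply(seq_len(nrow(spec$battery)), function(i) {
    p <- spec$profiles[[spec$battery$task_id[i]]]
    data.frame(task_id = spec$battery$task_id[i], label = p$label,
               grade = p$grade, theta_gain = p$theta_gain_frontal,
               alpha_gain = p$alpha_gain_parietal, stringsAsFactors = FALSE)
  }))
  lapply(seq_len(spec$n_subjects), function(s)
    list(recording = generate_recording(spec, s, montage), ground_truth = gt))
}

#' Simulate a rule-labeled archetypal DFHM set
#'
#' Generates head maps the way the hand-labeled training set looks:
#' tightly clustered around the three class archetypes (high: frontal mean
#' `+a`, parietal mean `-a`; low: mirrored; moderate: flat), where
#' `a = tau_high + margin` so the class archetypes are separated by at
#' least `margin` z-units in region-mean space. Each realized map is then
#' labeled by [auto_label()], so labels follow the rule exactly (zero label
#' noise). The within-class scatter defaults (region-mean shift sd 0.05,
#' per-electrode jitter sd 0.04 z-units) emulate visually unambiguous,
#' near-archetypal maps — the very local high-load kernel (width 0.3)
#' presupposes training maps clustered at about that scale.
#'
#' @param n number of maps (default 540).
#' @param margin archetype separation beyond the labeling threshold, in
#'   z-units.
#' @param rule the [label_rule()] used for labeling.
#' @param sd_shift sd of the per-map region-mean shift.
#' @param sd_eps sd of the per-electrode jitter.
#' @param montage the [dfhm_montage()].
#' @param seed RNG seed.
#' @return list of labeled `dfhm`.
#' @export
simulate_labeled_dfhm <- function(n = 540, margin = 1, rule = label_rule(),
                                  sd_shift = 0.05, sd_eps = 0.04,
                                  montage = default_montage(), seed = 1L) {
  set.seed(seed)
  a <- rule$tau_high + margin
  classes <- sample(rep(c("low", "moderate", "high"), length.out = n))
  frontal <- montage$regions == "frontal"
  lapply(seq_len(n), function(i) {
    F0 <- switch(classes[i], low = -a, moderate = 0, high = a) +
      stats::rnorm(1, 0, sd_shift)
    P0 <- switch(classes[i], low = a, moderate = 0, high = -a) +
      stats::rnorm(1, 0, sd_shift)
    vals <- ifelse(frontal, F0, P0) +
      stats::rnorm(length(frontal), 0, sd_eps)
    m <- vector_to_dfhm(vals, montage)
    m$label <- auto_label(m, rule)
    m
  })
}
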