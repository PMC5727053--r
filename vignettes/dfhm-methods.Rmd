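---
title: "The DFHM workload index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DFHM workload index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfhm)
```

## The problem and the model

Operators in safety-critical settings drift into overload (errors of
commission) or underload (vigilance decrements) long before behavioural
measures show it. EEG offers a continuous window on this: across a large
literature, rising task demands increase frontal-midline theta (4–8 Hz)
power and suppress parietal alpha (8–12 Hz) power. The Dual Frequency
Head Map (DFHM) approach turns these two signatures into a single
electrode-indexed object. Per 10 s segment, each electrode's theta and
alpha band powers are z-scored against the subject's own baseline
statistics, and one head map is assembled in which frontal electrodes
carry the theta z-score and parietal electrodes the alpha z-score. Two
binary RBF support-vector machines — a low-load detector and a high-load
detector — are applied to every map, and their outputs are combined
logically into a three-class index every 5 s.

The central assumptions, and what they buy:

* **Personal baselines remove inter-individual scale.** Absolute band
  power varies enormously between people (skull thickness, cortical
  folding, age). The z-transform against first-minute-of-each-task
  statistics makes maps comparable across subjects, which is what allows
  a classifier trained on one cohort to be applied to new subjects
  without retraining.
* **Region-band fusion removes task specificity.** A map keeps only the
  workload-relevant band per region, so tasks with very different
  perceptual content produce similar maps at similar demand levels.
* **Two one-vs-rest detectors plus a logical combination** avoid any
  quantitative threshold on band power at decision time; "moderate" is
  simply the absence of both extreme patterns.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| bandpass | 0.5–40 | Hz | retains theta/alpha, excludes mains & drift |
| FIR order | 100 | taps−1 | linear phase; group delay 0.1 s compensated |
| segment window / step | 10 / 5 | s | 0.1 Hz spectral resolution; 5 s index cadence |
| theta / alpha | [4,8) / [8,12) | Hz | half-open so the 8 Hz bin belongs to alpha only |
| baseline span | first 60 | s per block | varied demand without fatigue effects |
| labeling threshold τ | ±0.5 | z | codifies "pronounced" region means (see below) |
| SVM (low) | C=0.03, σ=3 | — | published, empirically selected |
| SVM (high) | C=0.03, σ=0.3 | — | published, empirically selected |
| MC-CV | 60/40 × 10 | — | random sub-sampling, retrain per split |

## Numerical choices

* **Filtering** is a Hamming-window FIR applied causally with explicit
  group-delay compensation, so results are deterministic and band power
  is undistorted. An order-100 FIR at 500 Hz has a transition band of
  roughly 16 Hz, which cannot realize a 0.5 Hz cut; the drift/DC
  rejection that the low edge intends is therefore implemented exactly,
  by removing each channel's mean before convolution. Very slow drifts
  (≪ 0.5 Hz but non-constant) are attenuated only mildly — a limitation
  shared by any short FIR at this rate.
* **Band power** uses one Hamming-tapered FFT over the full segment (no
  Welch averaging), with taper-power normalization `2/(N·Σw²)` so a unit
  sinusoid inside a band integrates to its mean-square power 0.5.
  Half-open bin assignment `[lo, hi)` keeps the band partition additive.
* **Baselines** use the sample (n−1) standard deviation, since the
  first-minute segments are a small sample of the subject's state space;
  zero variance at any electrode/band is an error (degenerate baseline),
  never silently accepted. Baselines include the rest blocks by default:
  the labeling set is defined over the ten task measurements, but the
  personalization statistics benefit from the widest available range of
  oscillatory states; `include_tasks` restricts this when needed.
* **Labeling rule.** The original head maps were labeled visually. We
  codify "pronounced" as a symmetric threshold on the two region means,
  τ = ±0.5 z. The value is the package's own choice and a config entry;
  the rule's structure (three-way partition, antisymmetric under sign
  flip) is tested rather than the specific τ.
* **Kernel convention.** σ is the width in k(x,y)=exp(−‖x−y‖²/2σ²);
  libsvm's γ is derived as γ = 1/(2σ²). The conflict case in the logical
  combination (both detectors firing) is mapped to *moderate* as the
  least-committal class; a config switch turns it into an error for
  auditing.
* **ICA** is Infomax, run from the identity rotation (deterministic, no
  random restarts); hitting the iteration cap is an error. Automatic
  artifact-component classification is lab-specific tooling; this
  package ships a documented heuristic (fronto-polar-dominated
  topography with sub-theta power concentration, or extreme kurtosis)
  behind a plug-in interface, and a `"none"` policy that bypasses
  rejection for clean synthetic data.

## The synthetic cohort: what it emulates, and what it does not

The generator produces 25-channel, 500 Hz recordings organized as the
canonical 81-minute battery (two rests and nine tasks; a `scale`
argument divides durations for desk-scale runs, flooring blocks at 60 s
so baselines stay well-defined). Each block superimposes, on per-channel
1/f backgrounds (exponent 1, rms 10 µV):

* a *shared* frontal theta oscillation (random 4–8 Hz frequency per
  block), amplitude-modulated by a smooth random burst envelope and
  scaled by the block profile's theta gain and a per-subject log-normal
  jitter;
* a *shared* parietal alpha oscillation (8–12 Hz), scaled by the alpha
  gain, mirroring the demand axis;
* optional blink transients (0.4 s raised-sine bumps, fronto-polar
  dominant) at a configurable rate.

Oscillation amplitudes (rms 6.6 µV theta, 5.1 µV alpha at gain 1) are
calibrated once so the signature-to-background band-power ratio is ≈ 2
under the moderate profile — strong enough to recover, weak enough that
classification is non-trivial. The burst-envelope depth (0.5) gives
band-power estimates realistic within-block variability, so baseline
standard deviations are never degenerate and occasional off-grade maps
occur, as in real EEG. Profile gains (theta 0.5 / 1.0 / 1.4 / 1.8 and
alpha 1.8 / 1.0 / 0.7 / 0.5 for low / moderate / stop-signal / high)
grade the demand axis; the stop-signal profile exists only as a held-out
block type for generalization tests.

What the generator does **not** emulate: volume conduction from dipolar
sources (signatures are injected at the channel level), non-stationary
artifacts other than blinks (muscle, electrode pops, sweat drifts),
band-power changes outside theta/alpha, fatigue or learning trends
within a session, and genuinely individual topographies. Passing
end-to-end tests therefore demonstrates that the pipeline's machinery —
filtering, decomposition, personalization, map construction,
classification, aggregation — recovers known ground truth under
realistic spectral statistics; it does not certify performance on human
EEG.

## The archetypal labeled-map simulator

The classifier benchmarks need a stand-in for the hand-labeled 540-map
training set. `simulate_labeled_dfhm()` draws maps tightly clustered
around the three class archetypes (frontal/parietal region means at
±(τ + margin), margin 1 z-unit by default) and labels each realized map
with the region-mean rule, so labels carry zero noise with respect to
the rule. The within-class scatter defaults (region-mean shift sd 0.05,
per-electrode jitter sd 0.04) encode a geometric observation: the
high-load detector's published kernel width, σ = 0.3, makes
k(x,y) = exp(−‖x−y‖²/0.18) vanish unless same-class maps lie within a
few tenths of a z-unit of each other in the 25-dimensional map space.
A width that local presupposes visually unambiguous, near-archetypal
training maps, and the simulator reproduces exactly that regime. Maps
produced by the full pipeline scatter much more widely (within-condition
z-spread ≳ 0.15 per electrode at the generator's calibrated
signal-to-background ratio), so for cohort-level evaluation the frozen
model pair is trained on auto-labeled pipeline maps with σ = 3 for both
detectors — kernel width is an empirical, data-scale parameter, and 0.3
is specific to archetype-scale clusters. Auto-labeled pipeline sets are
also strongly moderate-dominated; `balance_labeled_maps()` subsamples
them to equal class frequencies before training, emulating the curated
class coverage of a hand-labeled set (with C as small as 0.03, a
one-vs-rest SVM otherwise collapses to the majority class).

## Evaluation design

Cohort evaluation mirrors the no-retraining protocol: the model pair is
trained once, on a 4-subject training cohort (battery durations scaled
1/5), then applied unchanged to 8 new subjects whose battery additionally
contains a held-out stop-signal-like block the models never saw. Per
subject and task we compute the portions of low/moderate/high-load
segments, excluding the flagged training segment of each block (the
first complete window — the full-scale protocol excludes the whole first
minute, which at desk scale would empty 60 s blocks entirely). The
expected pattern, which the acceptance suite checks, is monotone
ordering of condition means: the portion of high-load segments increases
strictly from the low-workload to the high-workload conditions with the
held-out block falling in its graded position, and the portion of
low-load segments decreases strictly across the three generator
conditions (it saturates at exactly 0 for both top conditions, which no
strict four-way test can distinguish). Per-task portion tables feed a
one-way repeated-measures ANOVA with Greenhouse–Geisser-corrected
degrees of freedom (ε from the double-centered covariance matrix,
clamped to [1/(k−1), 1]) and Bonferroni-adjusted paired t post-hocs at
family α = 0.05 — paired t chosen as the conventional reading of
"multiple paired comparisons".

## Problem sizes

The test and acceptance runs use: 540 archetypal maps for the Monte
Carlo benchmarks; metadata-level cohorts of 54 subjects for training-set
bookkeeping; 4 + 8 full-signal subjects at 1/5-scaled battery durations
(≈ 17–19 simulated minutes each at 500 Hz) for the end-to-end ordering
check; and 30 s, 250 Hz recordings for ICA artifact-removal tests. These
sizes were chosen as the smallest at which each property is
demonstrated stably.

## Known limitations

* The 25-electrode montage is a reconstruction from the standard 10–20
  rows and is fully configurable; region membership of the central row
  is a convention (assigned parietal here).
* The ICA artifact policy is a heuristic stand-in validated on injected
  blinks only; users with real EEG should consider their lab's
  component-classification tooling via the plug-in interface.
* Absolute classification accuracies on synthetic maps say nothing
  about human-EEG accuracy; only the procedure (splits, retraining,
  averaging) is identical.
* EDF storage is 16-bit; round trips are exact only to quantization.
  BrainVision float32 storage is exact for re-reads.
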