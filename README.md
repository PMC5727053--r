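# dfhm — Dual Frequency Head Maps for EEG mental workload indexing

`dfhm` implements a continuous, subject- and task-independent index of
mental workload from multichannel EEG, built on two robust spectral
signatures of cognitive demand: frontal midline **theta** (4–8 Hz) power
rises with task demands, while parietal **alpha** (8–12 Hz) power falls.
The package targets neuroergonomics researchers and human-factors
practitioners who want a three-level (low / moderate / high) workload
read-out every 5 seconds from a standard 25-channel 10–20 recording,
without retraining anything for a new subject or a new task.

## Method

For a recording sampled at 500 Hz against Cz, the pipeline is:

1. **Pre-processing** — Hamming-window FIR bandpass (order 100,
   0.5–40 Hz, zero-net-delay), Infomax ICA with a pluggable
   artifact-component policy (default: fronto-polar, low-frequency or
   high-kurtosis components are removed), common-average re-reference,
   segmentation into 10 s windows overlapping by 5 s.
2. **Spectral features** — per segment and electrode, theta and alpha
   band power from a single Hamming-tapered FFT
   (P<sub>band</sub> = Σ<sub>f∈[lo,hi)</sub> |X(f)|², normalized so a
   unit sinusoid yields 0.5 µV²).
3. **Personalization** — per subject, electrode and band, a baseline mean
   μ and standard deviation σ are estimated from the segments of the
   first minute of every task; all powers are z-scored,
   z = (P − μ)/σ. These 4 values per electrode are the only
   subject-specific parameters.
4. **DFHM** — one head map per segment: frontal electrodes carry
   z<sub>θ</sub>, parietal electrodes carry z<sub>α</sub>.
5. **Classification** — two RBF SVMs (k(x,y) = exp(−‖x−y‖²/2σ²)) on the
   25-dimensional maps: a low-load detector (C = 0.03, σ = 3) and a
   high-load detector (C = 0.03, σ = 0.3), combined logically every 5 s:
   only-low → *low*, only-high → *high*, otherwise *moderate*.
6. **Summaries** — per task, the portions of low/moderate/high-load
   segments (LLS/MLS/HLS); across tasks, one-way repeated-measures ANOVA
   with Greenhouse–Geisser correction and Bonferroni-adjusted paired
   comparisons.

A synthetic EEG cohort generator (1/f background plus burst-modulated
frontal-theta and parietal-alpha oscillations whose amplitudes follow
per-task workload profiles, optional blink artifacts) makes the whole
pipeline testable without human data.

## Worked example

```r
library(dfhm)
mont <- default_montage()

# a frozen classifier pair: trained once, on rule-labeled maps from a
# 4-subject synthetic training cohort (battery durations scaled 1/5)
train_cohort <- generate_cohort(
  cohort_spec(4, default_battery(scale = 5), seed = 101, artifact_rate = 0))
maps <- balance_labeled_maps(
  cohort_labeled_maps(train_cohort, mont, artifact_policy = "none"), seed = 3)
models <- train_pair(maps, svm_config(0.03, 3), svm_config(0.03, 3))

# a new subject the models have never seen
rec <- generate_recording(
  cohort_spec(1, default_battery(scale = 5), seed = 11, artifact_rate = 0), 1)
sw <- subject_workload(rec, models, mont, artifact_policy = "none")

task_portions(sw$series[sw$series$task_id == "AOSPAN", ])
#>   pct_low pct_moderate pct_high n_segments
#> 1       0     43.47826 56.52174         46
task_portions(sw$series[sw$series$task_id == "0-back", ])
#>   pct_low pct_moderate pct_high n_segments
#> 1      40           60        0         10
```

Without any retraining, the AOSPAN-like block (the most demanding task
of the battery) shows a high-load-segment portion (HLS) of about 57%
and no low-load segments, while the easy `0-back` block shows the mirror
image (40% LLS, zero HLS) — the qualitative signature the index is
designed to recover.

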