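---
title: "Neural synchrony neuroforecasting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural synchrony neuroforecasting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosync)
```

This vignette is the package's account of its science: what each stage
computes, which parameters matter and why their defaults are what they
are, what the synthetic-study generator does and does not emulate, and
where the design was genuinely open.

## The pipeline at a glance

A panel of subjects listens to short music fragments while EEG is
recorded from nine 10/20 channels (F3, Fz, F4, C3, Cz, C4, P3, POz, P4)
at 256 Hz. Per (subject, stimulus) recording, the stages are:

1. **Preprocessing** — 50 Hz notch, 0.1 Hz high-pass, masking of
   samples whose amplitude strictly exceeds 400 µV;
2. **Band power** — sliding-window FFT periodograms on a 250 ms frame
   grid, averaged into the five canonical bands (delta 1–3, theta 4–7,
   alpha 8–12, beta 13–25, gamma 26–40 Hz);
3. **Metrics** — stimulus-level neural synchrony over C3/Cz/C4 alpha
   power, and frontal alpha asymmetry (FAA) from F3/F4;
4. **Group inference** — outlier gates, normality-gated correlations
   with Bonferroni control, popularity regressions with a
   diagnostic-gated log transform and nested-model F tests;
5. **Individual inference** — Kendall correlations with 1–5 likeability
   ratings and bidirectional stepwise AIC model selection.

`run_study()` chains all stages on a simulated study and records every
gate decision in its log.

## Preprocessing

The notch is a second-order IIR filter with a 2 Hz −3 dB bandwidth
(`notch_bandwidth_hz`); the high-pass is a Butterworth of order 4
(`filter_order`). Neither order nor bandwidth is dictated by the
measurement model, so the conventional EEG choices are used; both
filters run forward and backward so the net phase shift is zero, at the
cost of squaring the magnitude response (attenuation at 45/55 Hz stays
under 1 dB). At a 0.1 Hz cutoff the poles sit very close to the unit
circle: transients decay over tens of seconds, and floating-point noise
is amplified to roughly 10⁻⁶ relative — the package's linearity test
asserts at that tolerance, not machine epsilon.

Artifact handling is masking, not interpolation: samples where any
channel strictly exceeds `artifact_uv = 400` µV are flagged invalid and
the flag is extended by `guard_s = 0.25` s on both sides, so no 500 ms
band-power frame straddles an excursion edge. "Strictly exceeds" is
literal — a sample at exactly 400 µV survives. Interpolation was
rejected because it fabricates signal in exactly the windows the
correlation metric would then consume; whether an acquisition vendor
drops whole epochs or samples is unknowable from the outside, so
sample-wise masking with a guard band is this package's documented
choice. A recording with more than half its samples masked carries a
`quality_flag` and triggers a warning.

## Spectral decomposition

Each 500 ms window (128 samples at 256 Hz) is one Hann-tapered segment
— no sub-averaging, since a 500 ms sliding window advanced by 250 ms
leaves no room for it. The periodogram uses one-sided density scaling
(µV²/Hz), so band values are well-defined means over bins; the bin grid
at 128 samples is 2 Hz, and band membership is inclusive on bin centres
(alpha averages the 8, 10 and 12 Hz bins). Frame count follows
`floor((duration − window)/step) + 1`: a 24 s fragment yields 95
frames. Frames overlapping any masked sample keep their computed power
but are flagged `frame_valid = FALSE` and excluded from every
downstream average. Absolute power values depend on the taper and
normalisation, which acquisition vendors rarely publish; only the
structure of the series (ratios, correlations, identities) is treated
as meaningful.

## Neural synchrony

For each frame t with a full ±2-frame window and each ordered pair of
subjects (i, j), the two 5-frame × 3-electrode windows are flattened to
15-vectors (electrodes varying fastest) and Pearson-correlated; the
absolute correlations are averaged over the N(N−1) ordered pairs within
the frame, then over frames, and scaled by 100.

Design points, each of which was genuinely open:

* **Flattening.** Correlating two matrices only yields one scalar per
  pair-frame if they are vectorised; flattening to a 15-vector is the
  single reading consistent with that requirement.
* **Frame step.** The scalar metric steps one frame (250 ms). A
  coarser 1000 ms/500 ms smoothing is useful when *plotting* the time
  course and is exposed as `autoplot(result, smooth_frames = …)`, but
  never enters the scalar.
* **|·| placement.** The absolute value is applied per pair-frame
  correlation, before any averaging — anti-correlated responses count
  as synchronous.
* **Ordered pairs.** The N(N−1) denominator double-counts each
  unordered pair; for a symmetric kernel this equals the unordered
  mean and is kept for fidelity to the definition.
* **Edges.** Frames lacking a full ±2 window are skipped, not padded:
  a T-frame series contributes T − 4 windows. Pair-frames with zero
  variance are undefined, skipped and counted; frames with fewer than
  two valid ordered pairs are dropped.
* **Linear power.** Correlations are computed on linear band power.
  Log-transforming first would compress exactly the burst structure
  that carries the shared signal.

Under independence, the flattened windows behave approximately like 15
paired Gaussian draws, for which |r| has the closed-form mean
E|r| = (1/(k+1))/B(½,(n−2)/2) with k = (n−4)/2, i.e. 0.2171 at n = 15 —
so the null of the 0–100 metric sits near 21.7, not 0. Autocorrelated
band power raises that floor (smooth windows resemble ramps, and ramps
correlate); the package's null-calibration test therefore injects i.i.d.
values at the metric level, where the analytic value applies.

## Frontal alpha asymmetry

Per frame, ln(alpha power at F4) − ln(alpha power at F3); averaged over
valid frames per (subject, stimulus) and over subjects per stimulus for
group use. Frames where either power is non-positive are excluded with
a logged count. The identities FAA(p, p) = 0, FAA(p, e·p) = 1 and
channel-swap antisymmetry hold exactly and are asserted in the tests.

Engagement is a proprietary classifier probability and is only ever
*consumed* (`attach_engagement()` validates range and key
completeness); the package never computes it.

## Group-level inference

* **Outliers**: single-pass 3-SD rule with mean and SD from the full
  sample. Deliberately not iterated — a second extreme value unmasked
  by the first removal stays. The Mahalanobis screen (χ²₀.₉₇₅, p df)
  only flags rows for review.
* **Correlation gate**: Shapiro–Wilk on each variable at α = 0.05
  (conventional; the gate's operating characteristics are themselves
  tested). Pearson iff both pass, else Kendall's tau-b — tie-corrected,
  which matters for Likert ratings and small samples.
* **Bonferroni**: the group family defaults to m = 8 (two outcomes ×
  four predictors: ratings, synchrony, FAA, engagement), giving the
  0.006 threshold after 3-decimal rounding; the individual family is
  m = 2 (FAA, engagement), giving 0.025. Both are configuration, not
  constants.
* **Regression**: OLS with Shapiro-on-residuals and Breusch–Pagan. The
  log transform triggers when *either* diagnostic fails at 0.05 —
  which diagnostic should govern is underdetermined, so the
  conservative "either" is used and the decision is logged. On the log
  scale, E[Y|x] = exp(Xβ + σ²/2) under normal errors, so the
  interpreted per-unit multiplier is exp(b + σ̂²/2); it reduces to
  exp(b) as σ² → 0, and the tests cross-check it against an empirical
  mean ratio under simulated log-normal errors. Streams are kept in
  millions and must be positive before logging.
* **Nested models**: partial F on residual sums of squares; both fits
  must share outcome, rows and transform (the pipeline forces the
  extended model onto the base model's transform so the comparison is
  well-defined).

## Individual-level inference

Ratings are ordinal, so all likeability correlations use Kendall's
tau-b. The stepwise search is bidirectional from the intercept-only
model, taking at each step the single add/drop move with the largest
AIC decrease and stopping when none decreases it; the full trace is
retained and the final AIC can never exceed a visited model's. The
published analysis this mirrors ran a "stepwise logistic regression" on
a 1–5 outcome — a genuine ambiguity. Both readings are provided:
`family = "linear"` (default) fits OLS on the raw score;
`family = "logistic"` dichotomises at ratings ≥ 4. Perfect separation
in the logistic family falls back to linear with a warning and a flag.
Observations are pooled across subjects (no random effects), matching
the single pooled model being emulated.

## The synthetic-study generator

`simulate_eeg()` + `simulate_outcomes()` produce a complete study —
EEG, metadata, ratings, engagement, genre ranks, stream counts — as a
pure function of (config, seed), byte-reproducible. Defaults mirror the
study design this package models: 30 subjects × 24 fragments × 24 s at
256 Hz, nine channels, two artists with a 13/11 split and four
promotional singles each, and about 53% of subjects ranking pop first.

Each channel carries:

* a **shared stimulus-locked alpha component**: a per-stimulus envelope
  A_shared(t), identical across subjects, on a 10 Hz carrier with
  subject-specific phase;
* an **idiosyncratic alpha oscillation**: a subject-specific envelope on
  a subject-specific carrier in 8–12 Hz;
* **1/f (pink) noise** and broadband white noise;
* occasional square **artifact pulses** of 450–800 µV and 100–300 ms
  (unambiguously beyond the 400 µV gate) at `artifact_rate`/min.

Three generator choices deserve explanation because simpler variants
fail their purpose:

* **Energy-preserving coupling.** The coupling weight w enters as
  amplitudes √w and √(1−w), so total alpha power is independent of w
  and w moves power *between* the shared and idiosyncratic components.
  With linear weights, total alpha power (w² + (1−w)²) dips at
  intermediate w; the band-power autocorrelation changes with it, and
  the synchrony null level shifts enough to swamp weak coupling —
  the metric would not be monotone in w.
* **Band-limited envelopes.** Envelopes are Gaussian noise band-passed
  to 0.5–2 Hz. Energy below ~0.5 Hz makes a 1.25 s correlation window
  look like a monotone ramp, and independent ramps correlate
  spuriously, inflating the null; energy above 2 Hz would outrun the
  250 ms frame grid.
* **Log-normal bursts.** The band-passed noise is mapped through
  exp(·) with log-SD 1 and normalised to unit mean — the familiar
  waxing-and-waning of alpha. The resulting envelope contrast makes
  envelope-driven power fluctuations dominate band-power variance, so
  shared-envelope coupling (which scales as w² in the correlation) is
  resolvable at w = 0.3 without being trivially separable at w = 0.9.

The pink-noise RMS default (28 µV for a 24 s fragment) follows from an
alpha-SNR-of-1 calibration at w = 0.5: the shared component's power is
0.5 · alpha_uv² · E[A²]/2 ≈ 39 µV², and a 1/f spectrum puts a fraction
ln(12/8)/ln(128·24) ≈ 5% of its variance into 8–12 Hz, so
√(39/0.05) ≈ 28.

FAA is driven by scaling the F4/F3 alpha amplitudes by
exp(±valence/2 + subject offset); ratings come from a cumulative-logit
model with fixed cutpoints (−1.5, −0.5, 0.5, 1.5) whose latent scale is
centred on the same valence; engagement is a logistic transform of a
latent with a negative valence loading (so engagement falls as liking
rises), plus observation noise, clipped to [0, 1]. Stream counts follow
log(streams) = β₀ + β_synch · s(w) + β_single · single + ε with
s(w) = 25 + 10w (a noise-free synchrony proxy on the metric's percent
scale), β₀ = −19, β_synch = 0.7, β_single = 0.75, σ = 0.3, and a late
horizon equal to the early one scaled by 3.2 with extra log-normal
noise. These defaults put streams in single-digit to tens of millions
with a log-scale spread near 1 — the regime the analysis is meant for.

**What the generator does not emulate**: scalp topography and volume
conduction (channels share a source but have no geometry), ocular or
muscle artifact morphology (only amplitude excursions), any real
engagement classifier, or genre-dependent taste structure. Passing
parameter-recovery tests on this generator shows the *analysis chain*
is correct and well-calibrated; it cannot certify performance on real
EEG, whose noise is richer and whose effect sizes are smaller.

## Problem sizes and numerical conventions

The test suite runs the full default study (30 × 24 × 24 s) for the
end-to-end determinism check and scales other simulations to what a
property needs: coupling monotonicity uses 8 subjects × 3 stimuli ×
24 s per coupling level over 20 fixed seeds (the paired design leaves a
w = 0 → 0.3 mean gap of ≈ 4 synchrony points against a paired SD of
≈ 1.5); the FAA–valence property uses 8 subjects × 24 stimuli × 12 s
with only F3/F4 simulated; parameter-recovery replicates reuse the
outcome model at 2-subject EEG scale since only the tables matter
there. Tolerances follow the quantity: exact identities at 10⁻¹²–10⁻⁶,
the synchrony null at 2% relative, Monte-Carlo rates with margins wide
enough for their own sampling error at the fixed seeds. CSV output
writes doubles with 17 significant digits and reads them back through
strtod, which round-trips bit-exactly; EDF quantises to 16 bits over
±1000 µV (step ≈ 0.031 µV). All reported JSON carries full precision;
human-readable prints round to 3 decimals.

## Known limitations

* Absolute band-power values (and hence absolute synchrony levels on
  real data) depend on taper and normalisation conventions and are not
  comparable across implementations; structure is.
* The stepwise search is greedy; it provably attains the all-subsets
  minimum only usually (the tests quantify "usually" at ≥ 95% on
  five-candidate problems).
* No mixed-effects or ordinal-regression variants at the individual
  level; no robust regression; no Spearman option — all deliberate
  scope choices.
* The EDF reader targets the package's own EDF+C layout (one annotated
  continuous file per subject); it is not a general-purpose EDF parser.
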