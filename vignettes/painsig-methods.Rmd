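---
title: "Methods: biopotential feature patterns for pain-intensity recognition"
author: "painsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biopotential feature patterns for pain-intensity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(painsig)
```

## The problem

Phasic heat pain elicits graded autonomic and somatomotor responses: facial
muscle activity (zygomaticus, corrugator), shoulder muscle tone (trapezius),
electrodermal activity (skin conductance level, SCL) and cardiac changes
(shortened interbeat intervals). **painsig** implements an automated
pain-intensity recognition pipeline over these five biopotential channels:
protocol-structured data (simulated), preprocessing, a 159-dimensional
feature space, two-stage feature selection, and RBF-kernel SVM classification
with Cramér's V as an effect-size validity measure.

The experimental design being emulated: each subject receives four
individually calibrated temperature levels — T1 (pain threshold) through T4
(pain tolerance) — each applied 20 times in randomized order (80 stimuli),
with 4 s plateaus and randomized 8–12 s pauses; baseline is 32 °C. The
classification unit is a 5.5 s window: one "pain window" anchored at each
stimulus onset (the plateau plus 1.5 s of the response tail; the anchor is a
design choice, as only a graphical description of the window placement
exists) and 20 stimulus-free "non-pain windows" (class B), which we centre in
pauses at least 1.5 s after the previous plateau ends. Each subject thus
contributes 100 labelled windows; 85 subjects give 8 500 windows, and the
stratified 75/25 split yields 6 375 training and 2 125 test vectors.

## The synthetic-data generator

No real recordings are required: `simulateSubject()` / `generateDataset()`
generate the full protocol per subject from a single master seed
(per-subject substreams are hash-derived, so any subject regenerates in
isolation). The generative model is intentionally simple — it reproduces the
*statistical structure that the features measure*, not biophysical waveform
morphology:

* **EMG** (zygomaticus, corrugator, trapezius): zero-mean Gaussian noise
  band-limited to 20–250 Hz. During each stimulus the noise scale is
  multiplied by a level-dependent burst gain (defaults 1.15, 1.5, 2.1, 2.8
  for T1…T4) with smooth cosine on/off ramps; the trapezius retains half of
  the facial effect. Three sources of realism keep the task honestly hard:
  (i) per-trial log-normal response variability (sd 0.9 on the log scale,
  mean 1) — many individual stimuli evoke little or no facial response;
  (ii) a slow (~30 s correlation) log-normal drift of resting muscle tone
  (sd 0.35); (iii) spontaneous bursts unrelated to stimulation (3/min).
* **SCL**: a tonic level with stochastic slow drift (0.15 µS sd), plus one
  phasic skin-conductance response per stimulus: onset latency uniform in
  1–3 s, exponential rise (τ ≈ 0.7 s) and decay (τ ≈ 3 s, jittered),
  amplitude set by the level (0.2, 0.6, 1.2, 2.0 µS) with the same per-trial
  variability, plus spontaneous SCRs (2/min).
* **ECG**: a biphasic QRS-like template train. RR intervals follow an AR(1)
  process around the subject's mean RR (850 ms, SDNN 40 ms); inside stimulus
  windows the mean RR is shortened by 8, 20, 40, 60 ms (T1…T4) with 20 ms
  per-trial noise.

Per-subject log-normal baseline scales (EMG noise floor, tonic SCL, mean RR)
make the per-person z-normalization non-trivial.

**Calibration.** The effect sizes and variability parameters above were fixed
once so that the synthetic benchmark reproduces the *difficulty structure*
reported for the real protocol — baseline vs pain threshold is markedly
harder than baseline vs pain tolerance, with two-class performance in the
high-70s to mid-90s percent range — and were not revisited afterwards.

**What the simulator does not emulate**: realistic motor-unit EMG or ECG
morphology, thermode temperature dynamics, electrode artifacts, movement
artifacts, or inter-channel physiological coupling beyond the shared
stimulus schedule. Passing the acceptance checks on synthetic data therefore
demonstrates that the pipeline recovers planted class structure of the kind
the features measure — it does not certify performance on real recordings.

## Preprocessing

1. **Butterworth filtering**, EMG 20–250 Hz and ECG 0.1–250 Hz. Zero-phase
   filtering is implemented by applying the squared magnitude response of the
   high-pass/low-pass Butterworth cascade in the frequency domain with mirror
   padding. This is exactly the ideal forward–backward response — zero phase,
   no start-up transients — and is stable for the nearly full-band ECG
   specification. If the upper edge reaches Nyquist it is clipped to
   0.99 × Nyquist with a warning.
2. **EMD denoising** of each EMG segment: sifting with natural-cubic-spline
   envelopes (stop when the sift correction energy falls below 5 % of the
   residue, at most 10 sifts, at most 6 IMFs). Leading IMFs are discarded
   while they are consistent with broadband noise under the white-noise
   energy model E₁/β^(k−1) (β = 2.01, anchored on a robust MAD estimate of
   IMF-1 energy) **and** spectrally flat (normalized spectral entropy
   ≥ 0.5). The flatness guard is needed because a noise-free narrowband
   signal concentrates in IMF 1 and is always "consistent" with an energy
   model anchored on itself; without the guard a clean tone would be deleted.
3. **Burst detection** (diagnostic): analytic-signal envelope (FFT Hilbert
   transform), 50 ms moving-average smoothing, threshold median + 3.5 MAD,
   minimum duration 0.1 s. These parameters are not printed in the protocol
   description; they were chosen to give high hit rates and ≤ 5 % false
   positives on the simulator's bursts.
4. **QRS detection**: smoothed squared first difference (80 ms window),
   adaptive threshold, 250 ms refractory period; RR intervals in ms.
5. **Windowing** as described above. SCL is not band-pass filtered; it is
   linearly detrended per window before the frequency and stationarity
   feature groups.

## The feature space

Each of the four waveform channels (three EMG, SCL) contributes 39 features
in seven mathematical groups; the ECG contributes three heart-rate-
variability features, giving 4 × 39 + 3 = 159 with group sums
40 amplitude / 24 frequency / 24 stationarity / 20 entropy / 8 linearity /
19 variability / 24 similarity. This channel-to-group mapping is the unique
one consistent with the printed group sums. Names follow
`Channel_Group_Feature` (e.g. `Zygomaticus_Similarity_Correlation`).

Numerical choices that the analysis depends on:

* **Entropies** (approximate, sample, fuzzy): m = 2, tolerance r = 0.2 sd,
  fuzzy exponent 2 — standard literature values. They are computed on a
  4×-decimated copy of the segment (~128 Hz, N = 704): template entropies of
  a ~2 800-sample broadband segment are dominated by noise at O(N²) cost,
  and the decimated series retains the regularity structure the features
  rank. Approximate entropy includes self-matches (the original convention);
  sample entropy excludes them; fuzzy entropy uses baseline-removed
  templates with weight exp(−(d/r)²). All logarithms are natural; Shannon,
  spectral and mutual-information values are in nats (16 histogram bins).
* **Spectral estimates**: 256-sample Hann frames with 50 % overlap, both for
  the Welch coherence estimates and for the spectrogram behind the
  stationarity degree DS(ω) = mean over frames of (1 − H(ω,t)/h(ω))², with
  h(ω) the frame-mean density. The four DS aggregates (median,
  frequency-weighted mean, area, power-weighted area) are this package's
  definitions — the source material names them without formulas. The me/sd
  stationarity pair uses 0.5 s subsegments.
* **Central frequency**: the textual definition (fh + fl)/2 (mean of the
  band-edge frequencies) is the default; the printed variant (fh − fl)/2 is
  available as `featureConfig(cfPrinted = TRUE)`. Both are exposed because
  text and formula disagree in the source material.
* **Lag-dependence** (linearity): for lags k = 1…10, R²(k) of the linear and
  of the quadratic regression of x(t) on x(t−k); the feature is the mean of
  √max(R², 0). The quadratic nests the linear fit, so the "polynomial"
  variant is never smaller.
* **Coherence aggregates**: magnitude-squared coherence (the printed formula
  omits the modulus, but non-squared coherency is complex and cannot be
  aggregated); on the uniform frequency grid the power-weighted *area*
  coincides with the power-weighted *mean* up to the trapezoidal end
  correction, and redundant aggregates are removed later by correlation
  pruning anyway.
* **Similarity reference**: the subject's element-wise mean baseline
  segment. For a baseline window itself the reference is the leave-one-out
  mean of the *other* baseline windows: a window must never be compared
  against a reference containing itself, otherwise every baseline window
  carries a detectable self-match and the similarity features degenerate
  into a label oracle. (With iid synthetic noise this artifact is strong
  enough to drive two-class accuracy to 1.0.)
* **Local extrema** (mlocmaxv/minlocminv): strict sign changes of the first
  difference; plateaus contribute their first sample.
* **Degenerate values** (e.g. RR features of a window with too few beats,
  frequency features of an all-zero spectrum) carry NA sentinels; features
  containing sentinels are removed by the static-pruning stage.

All features are z-transformed per person; features constant within a
subject are set to 0 and flagged static.

## Feature selection and classification

Selection is two-stage, computed on training data only:

1. **Manual pre-selection**: drop static/degenerate features, then greedily
   drop any feature whose |Pearson r| with an already-retained feature is
   ≥ 0.95 (the earlier feature in canonical order is kept — the source does
   not specify which member of a pair was deleted).
2. **Wrapper forward selection**: starting from the empty set, each round
   adds the candidate that maximizes 3-fold cross-validated accuracy (ties
   to the lowest column index) and stops at the first round with no strict
   increase. The inner classifier is an RBF-SVM with (C, γ) fixed by a
   coarse 3 × 3 grid on the full candidate set; nesting a full grid search
   inside every wrapper round is not specified in the source design and
   would be prohibitively slow, so the full exponential grid
   (C = 2⁻⁵…2¹⁵, γ = 2⁻¹⁵…2³, steps of 2²) is re-tuned once on the selected
   subset, again by 3-fold CV (ties to smaller C, then smaller γ).

The final model is refit on all training data and evaluated once on the
held-out 25 %: accuracy, per-class sensitivity and specificity (one-vs-others
for more than two classes), and Cramér's V of the confusion table with the
conventional association bands (0.1/0.2/0.4/0.6/0.8). The train/test split
is stratified by class, which makes the 6 375/2 125 arithmetic exact; an
optional `groupBySubject` split holds out whole subjects instead (the
source material does not state which policy was used; window-level
stratification is the default and measures within-subject generalization).

## Problem sizes and reproducibility

The acceptance harness (`scripts/acceptance.R` and the acceptance tests)
uses a 10-subject synthetic cohort — 1 000 windows, 159 features — for the
learning-stage checks, and a second cohort with all class effects zeroed for
the null checks; these sizes were chosen so a full reproduction runs on a
laptop-class single core in minutes. Because single null-run test accuracy
on ~100 test windows has sampling noise of about ±0.05, the null checks use
the median over five seeded learning runs. The monotone-difficulty check
varies the learning-stage seed (split, folds, selection) over ten values on
the fixed seeded cohort. Every random element in the package derives from
one master seed via `deriveSeed()`.

## Known limitations

* The simulator's class signal lives mostly in amplitude-scale, SCR-shape
  and RR-shift structure; features whose real-data value comes from waveform
  morphology (e.g. EMG spectral shape changes under fatigue) carry little
  information here.
* Because the simulated EMG *is* amplitude-modulated broadband noise, the
  EMD denoiser classifies all of its IMFs as noise-consistent and keeps
  mainly the slow residual; the class-carrying amplitude modulation survives
  (per-window amplitudes of denoised and filter-only segments are strongly
  rank-correlated), but EMG spectral features describe the residual rather
  than the 20–250 Hz band. On real EMG, whose modes are not white, the same
  rule removes only the leading noise-like scales.
* Entropy features are nearly scale-invariant by construction (r ∝ sd), so
  on amplitude-modulated synthetic noise they contribute less than they may
  on real signals.
* Window-level splitting shares subjects between training and test sets;
  with temporally correlated features this measures within-subject
  generalization, not subject transfer (use `groupBySubject = TRUE` for the
  latter).
* The EMD implementation uses natural spline envelopes with clamped ends;
  end effects are mitigated but not eliminated, as in most practical EMD
  variants.
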