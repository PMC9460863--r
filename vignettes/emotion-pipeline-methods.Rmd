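---
title: "Methods: from physiological signals to emotion-driven interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from physiological signals to emotion-driven interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoglove)
```

This vignette is the package's own account of its methods: the signal model
and judgment procedure, the parameters that matter and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the numerical and design choices made where the problem left them open.

## 1. The recognition model

Two physiological channels are used. The **skin-electrical signal**
(galvanic skin response, 20 Hz) is a slow conductance trace with a tonic
level, a possible drift, and phasic skin-conductance responses (SCRs). The
**pulse wave** (photoplethysmogram, 100 Hz) shows, per beat, a systolic main
wave, a falling-limb shoulder (dicrotic anterior wave), a dicrotic notch,
and a dicrotic wave.

Emotion is classified into the four valence–arousal quadrants (HAPV, HANV,
LANV, LAPV) by a deterministic rule cascade over three features:

* `bpnn50` — percentage of successive beat-interval differences strictly
  greater than 50 ms. The one-line definition this statistic descends from
  ("percentage of main pulse wave interval > 50 ms") is ambiguous; we adopt
  the standard pNN50 reading — it is the only one in which the 50 ms
  constant has an established meaning. Strict (`>`, not `>=`) counting is
  used; the boundary case is tested.
* `range` — max − min of the **denoised, pre-normalization** segment. The
  source material glosses "range" with the same words as `1dmean`; since a
  per-segment 0–100 min–max normalization forces the range of a normalized
  segment to a constant 100, the only informative reading computes it
  before normalization, with max − min as the standard meaning of the word.
  Both statistics remain separately available.
* `d1mean` — mean first-order difference; telescopes to
  `(last − first)/(n − 1)` exactly, which the tests assert.

Because the skin-electrical range is elevated under two *opposite*
emotional trends, the cascade adds a **directional judgment**: the sign of
the least-squares trend slope with a dead band (below, §3). The cascade:

1. if normalized range ≥ θ_A: arousal = high if direction ≥ 0, else low;
2. else: arousal = high iff normalized `d1mean` ≥ θ_1d;
3. valence = positive iff normalized `bpnn50` ≥ θ_V.

This cascade is a *reconstruction*: the process diagram it implements is
referenced but not printed in the source material, so the decision logic
here is this package's own, stated plainly and swappable — `judge_segment()`
accepts a replacement `rules` function. Two boundary conventions are fixed
and tested: ties at a threshold take the `≥` branch, and `direction == 0`
(flat) is grouped with the rising branch.

## 2. Preprocessing

**Wavelet denoising** (`denoise_gsr`): periodized Daubechies-4 DWT, 5
levels (capped at `log2(n/4)` for short inputs), soft thresholding of all
detail bands at the universal threshold `sigma * sqrt(2 log n)` with
`sigma` the MAD of the finest detail band. The transform family was given;
wavelet, depth and threshold were not — db4/5-level/universal-soft is the
textbook configuration for slow biosignals with broadband noise. Inputs of
arbitrary length are reflection-padded to a multiple of `2^levels` and
truncated after reconstruction, so length and sampling rate are preserved
(asserted for lengths 64, 100, 601). Soft thresholding shrinks orthonormal
coefficients, so output energy cannot exceed input energy.

**Butterworth low-pass** (`lowpass_pulse`): order 4, cutoff 10 Hz at
fs = 100 Hz, applied forward–backward so the filter is zero-phase —
fiducial-point *times* are the measurement, so phase distortion is not
acceptable; the tests bound the post-filter systolic peak shift at one
sample. The underlying `signal::filtfilt` applies no edge padding, so the
wrapper adds odd-reflection padding of `3 * fs / cutoff * order` samples,
inside which the startup transients decay (DC traces pass through to
~1e-7).

**Normalization** (`normalize_segment`): per-segment affine min–max map to
[0, 100] exactly; idempotent, strictly monotone (argmin/argmax preserved).
Constant segments are rejected with a `degenerate_input` error rather than
silently mapped — range and direction are undefined on them and letting
them through would poison the calibration table.

**Segmentation** (`segment_stream`): half-open windows
`[k·hop, k·hop + window)`, final partial window dropped. The default window
is 30 s — the nominal duration of one emotion-inducing stimulus.

## 3. Feature extraction parameters

* `refractory_ms = 300` (beat detection): two systolic peaks closer than
  300 ms would imply > 200 bpm; the value is the standard artifact guard.
* `min_height_frac = 0.55`: the dicrotic wave is generated at 40% of
  systolic amplitude, so a threshold at 55% of the amplitude range sits
  between the two peak families with margin on both sides.
* Beat intervals are measured systolic-peak-to-peak, not onset-to-onset:
  on noisy pulse traces the peak is the stabler landmark.
* Fiducial shoulder points `d` and `f` (which have no operational
  definition in the source material) are located as extrema of the first
  derivative: `d` is the least-steep point of the falling limb between the
  systolic peak `c` and the notch `e`; `f` the steepest point of the rise
  between `e` and the dicrotic peak `g`. A beat with no post-peak local
  minimum has no notch and is returned flagged `degenerate`, with `h3`,
  `h4`, `t2` missing, rather than inventing landmarks.
* `dead_band` for the directional judgment defaults to 1% of the segment
  standard deviation per sample. This decouples direction from `d1mean`
  (which sees only the endpoints) and keeps flat-plus-noise segments at
  direction 0 (asserted at ≥ 90% over 100 draws). Under the default
  synthetic conditions the per-sample slope of a drifting segment can fall
  inside this dead band, making direction 0 — harmless here because the
  cascade groups 0 with the rising branch, but worth knowing when
  re-tuning: the dead band is in a.u. *per sample*, so it scales with the
  sampling rate.
* The auxiliary feature pool is fixed to 8 named time-domain statistics
  (`auxiliary_feature_names()`): mean, SD, skewness, mean |first
  difference| and IQR of the skin-electrical segment; mean, SDNN and RMSSD
  of the beat intervals. They exist to give PCA selection a realistic
  search space. Frequency-domain features are out of scope — none is named
  in the source material.

## 4. Calibration

Features are standardized (zero mean, unit variance) before PCA; the
smallest leading set of components reaching `variance_keep = 0.85`
cumulative explained variance is retained, and a feature is selected iff
its maximum absolute loading over the retained components is at least
`weight_threshold = 0.6` (at least one feature is always selected). Both
cut-offs are unstated upstream and config-exposed.

A structural caveat worth stating honestly: PCA-loading selection on
*standardized* features sees only the correlation structure. An eigenvector
entry of 0.6 or more concentrates a component on at most ~2 features
(entries of a k-feature block scale as `1/sqrt(k)`), and an independent
noise feature owns an eigenvalue-≈1 component of its own that a
high-variance-keep cut will retain. Consequently this selector
distinguishes *correlated feature blocks* from isolated features; it cannot
suppress an isolated noise feature while `variance_keep` is high. The tests
exercise the realizable behavior (a correlated signal pair selected,
isolated noise excluded under a first-component cut); the judgment stage
does not depend on the selector because the three optimal features are
always carried into the model.

`pcc_emotion` correlates each feature with the one-vs-rest indicator of
each quadrant — the only way a categorical quadrant can enter a Pearson
correlation without further assumptions — with two-sided P from the
t-transform of r on n − 2 degrees of freedom. No multiple-testing
correction is applied (none is applied upstream); `alpha = 0.05` is
recorded in the model. A brute-force covariance-formula oracle reproduces
r and P to 1e−10 in the tests.

Thresholds are midpoints of class-conditional *medians* of the min–max
normalized features (high- vs low-arousal classes for θ_A and θ_1d,
positive- vs negative-valence classes for θ_V). Midpoint-of-medians was
chosen over midpoint-of-means for outlier resistance; the upstream material
says only that thresholds are "determined". θ_A by construction depends
only on the arousal partition (asserted by swapping the two high-arousal
labels).

## 5. The synthetic generators

The generators define the study conditions; they are first-class, tested
code, not fixtures.

**Skin-electrical** (`gen_gsr`): tonic baseline (5 a.u.) + signed linear
drift + SCRs at Poisson times with bi-exponential shape (rise τ = 0.75 s,
decay τ = 2.0 s — standard SCR morphology), amplitudes log-normal around
the preset mean, + Gaussian noise (SD 0.05 a.u.). The time grid spans
`[0, duration]` inclusive so a pure trend rises by exactly
`slope × duration`.

**Pulse wave** (`gen_ppg`): each beat is two Gaussian bumps — systolic, and
a dicrotic bump at 35% of the beat interval after it with 40% amplitude —
the minimal shape exhibiting all the named landmarks (onset, systolic peak,
shoulder, notch, dicrotic wave). The systolic peak sits at a *fixed* offset
(0.18 × mean interval) after each onset so peak-to-peak intervals equal
the generated onset intervals exactly. Beat intervals follow a bounded
random walk whose steps are 65 ms with probability `hrv_pnn50_target` and
15 ms otherwise: the fraction of successive differences above 50 ms then
approximates the target, with the 65/15 ms values leaving margin on both
sides of the threshold for the ±10 ms quantization of a 100 Hz trace.

**Default presets** encode the pipeline's own working assumptions — high
arousal ⇒ dense large SCRs (rate 10/min, amplitude 1.0 a.u.) and rising
drift (+0.06 a.u./s); low arousal ⇒ sparse small SCRs (2/min, 0.3 a.u.)
and mild negative drift (−0.02 a.u./s); positive valence ⇒ high BpNN50
target (0.60/0.65), negative ⇒ low (0.10/0.15); heart rates 90/95/70/65
bpm. These close the parameter-recovery loop and are documented as
synthetic constructions, **not** physiological truth: real electrodermal
and cardiac responses to emotion are weaker, subject-specific, and
confounded; passing recovery tests shows the pipeline's internal
consistency, not field validity. `default_presets(separation)` shrinks all
presets toward their mean, providing the separability dial used to show
that recognition accuracy degrades as the quadrants converge.

**Glove streams** (`gen_glove_stream`): finger-bend tuples are converted
bend → resistance (inverse piecewise-linear calibration) → ADC count →
frame bytes; IMU angles are quantized to signed 16-bit words at
180°/32768 per LSB. Decoding recovers inputs within one quantization step
(property-tested over 100 random tuples).

## 6. The glove protocol

* The divider equations are read as `x = round(V_x · 4096 / 3.3)` and
  `V_x = 3.3 · R / (R + 20 kΩ)` — a 12-bit ADC at 3.3 V with a 20 kΩ
  divider is the only reading consistent with both collapsed typeset
  fractions. At the three printed calibration resistances this gives
  counts 1271 / 1687 / 2146 (independent arithmetic: `4096·9/29` etc.).
* The exact inverse `R = 20·x/(4096 − x)` carries the quantization floor
  of the rounding: half an LSB propagated through the divider is ≈
  0.011 kΩ near 22 kΩ, so count 2146 inverts to 22.0103 kΩ. This is not
  an implementation artifact; no inverse of a rounded count can do better.
* The stated claim that counts are *inversely* proportional to bending
  contradicts the divider equation (monotone increasing in R, and R grows
  with bending). The equations win; `sensor_model(inverted = TRUE)` flips
  the relation for hardware that behaves the other way.
* Finger frames: the 7-token schematic `0xaa a1…a5 0xbb` cannot carry
  12-bit counts in single bytes. The default (`"wide"`) codec carries each
  count as two bytes little-endian (12-byte frame); a `"strict7"` mode
  right-shifts counts to 8 bits and emits the literal 7-byte layout. This
  is a declared dialect decision.
* IMU packets: 11 bytes, header 0x55, type 0x51/0x52/0x53, three signed
  little-endian words, TL/TH auxiliary word (parsed, preserved,
  uninterpreted), and SUM = low byte of the sum of the preceding 10 bytes
  — the checksum equations produce a sum wider than a byte and low-byte
  truncation is the convention for this frame family. A single-byte
  change of any of the 10 summed bytes shifts the sum by a nonzero amount
  mod 256, so *every* single-byte corruption is detected (verified
  exhaustively: 3 packet types × 10 positions × 255 values). Physical
  scale factors (÷32768 × 16 g / 2000 °/s / 180°) are the de-facto
  convention for this packet layout and are config-exposed.
* The stream parser resynchronizes byte-by-byte after garbage, counts
  checksum failures, and flags (never silently drops) finger frames whose
  decoded bends are implausible (outside [0°, 180°] ± 5°).

## 7. Interaction layer

Fixed bijections map quadrants to animation gestures ("1"–"4" for HANV,
LANV, HAPV, LAPV) and to steering directions (up, left, right, down). The
timing-deviation metric between the emotion-driven virtual-hand events and
the glove-driven manipulator events is
`100 · (t_manipulator − t_virtual) / stimulus_duration`, with the 30 s
stimulus duration as denominator — the only duration available to a
percentage of this kind; a config switch allows the virtual-event latency
instead. The sign convention (manipulator minus virtual) is declared, not
inferred. Event matching is greedy in-order by gesture id; unmatched events
are reported as missing rather than dropped, mirroring the "no response"
cells a hardware run can produce. Emotion events are stamped at the end of
the judged window, since a window's features are not complete before it
closes.

## 8. Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
recovery accuracy uses 100 segments per quadrant at full preset separation
and 40 per quadrant at the two reduced separations (0.5 and 0.25); codec
properties use 100 random frames per family plus the exhaustive flip scan;
the oracle comparison uses 50 random tables of up to 50 segments. These
sizes give stable estimates (binomial SE ≈ 1% at n = 400) while keeping a
full run under a minute on one CPU. All randomness flows from one run seed
through a documented per-module derivation (`seed` + a hash of the module
name, kept below 2^31), so identical seeds give bit-identical outputs; no
global RNG state leaks (`with_seed` restores the caller's state).

## 9. Known limitations

* The judgment cascade is a stated reconstruction of an unpublished
  flowchart; alternative readings plug in via `rules`.
* The generators are shape-level emulations; no claim of physiological
  validity is made, and results on them bound nothing about human data.
* PCA-loading selection cannot suppress isolated noise features at a high
  cumulative-variance cut (§4).
* Frequency-domain features, EDA tonic/phasic decomposition as an output,
  learned classifiers, and cross-subject transfer are out of scope.
* The resistance inversion carries the 12-bit quantization floor (§6).
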