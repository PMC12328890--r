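---
title: "Measuring vertical larynx kinematics and oral-laryngeal timing from real-time MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vertical larynx kinematics and oral-laryngeal timing from real-time MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larkin)
```

## The measurement problem

Non-pulmonic consonants — ejectives and implosives — are produced by raising
or lowering a closed larynx to change intraoral air pressure. Quantifying
that vertical larynx action, and its timing relative to the oral closure
gesture, requires a signal that standard articulometry does not provide:
the larynx is not a constriction-forming articulator, so there is no fixed
place in the vocal tract where "more tissue" means "more gesture".
Dynamic mid-sagittal MRI shows the moving larynx directly, and `larkin`
implements the two complementary measurement techniques this calls for:

* **Region-of-interest (ROI) intensity series** for oral constrictions:
  a small pseudo-circular region is placed where the constriction forms
  (lips, alveolar ridge, velum); its mean pixel intensity rises as tissue
  fills the region, giving a per-frame scalar proxy for constriction
  formation.
* **Intensity-weighted centroid tracking** for the larynx: inside a fixed
  rectangular vocal-tract region (VTR) tall enough to contain the full
  vertical excursion, every frame is segmented into connected components
  of bright pixels; each component's intensity-weighted centroid
  (`sum(I * x) / sum(I)` per axis) is a sub-pixel position estimate, and
  the track follows the component closest to the previous frame's
  centroid, seeded by a user-supplied point in frame 1. The continuity
  rule is what keeps other bright structures that drift into the VTR from
  capturing the track.

Both signals are then annotated with velocity-threshold landmarks
(movement onset ONS, peak velocity PVEL, target onset TONS, maximum MAX,
target offset TOFF, at 20 % of the relevant velocity peak), from which the
derived measures follow: signed larynx displacement (position at MAX minus
position at ONS), larynx extremum (absolute position at MAX), onset lag
(larynx ONS minus oral ONS), target lag (larynx ONS minus oral TONS), and
larynx duration (TOFF minus ONS). Positive lags mean the larynx starts
after the oral landmark.

## Acquisition geometry

The default `acquisition_spec()` encodes the protocol the package
emulates: a 200 mm field of view reconstructed on an 84 × 84 grid
(2.38 mm pixels), a 13-interleaf spiral sequence with TR = 6.004 ms (each
fully sampled image spans 78.052 ms), and a 2-TR sliding-window
reconstruction giving an effective rate of 1000/(2 × 6.004) ≈ 83.3
frames/s (12.008 ms per frame). All spatial conversions in the package go
through `px_size_mm`; all timestamps through `frame_period_ms`.

```{r geometry}
acquisition_spec()
```

## What the synthetic data emulates — and what it does not

No imaging data accompany the study this package models, so the package
ships a first-class simulation module with two outputs.

**Phantom videos** (`render_phantom_video()`) place a bright elliptical
raised-cosine blob (`I = peak * cos(pi * rho / 2)`, default semi-axes
2.5 × 5.5 px) on a dark background and move it vertically along a
closed-form cosine-ramp gesture; an oral "tissue" block with an
anti-aliased edge can slide into a fixed ROI, and extra blobs can act as
distractors. The cosine ramp was chosen because its velocity has a single
peak `A*pi/(2*T)` at the transition midpoint and its 20 % crossings are
analytic (onset at `(T/pi)*asin(0.2) ≈ 0.0641*T` after movement start), so
every landmark the pipeline should find is known in closed form
(`gesture_landmark_times()`). For the oral channel the ground truth is the
landmark set of the *region-intensity* signal, which is a known
(coverage-model) function of the tissue trajectory; the test suite
evaluates that model densely (0.25 ms grid) as an oracle independent of
the rendering/tracking path.

What the phantoms deliberately do not model: spiral k-space sampling and
constrained-reconstruction artifacts, coil shading, through-plane motion,
swallowing and head drift, and the anatomical complexity that makes real
VTR crops contain several articulated structures. Noise is additive
Gaussian by default (`noise_model = "rician"` is available; at the
signal-to-noise ratios used here the difference is immaterial).
Consequently, green phantom tests certify the *algorithmic* chain —
segmentation, centroid arithmetic, continuity, smoothing, landmark logic —
not robustness to scanner physics.

**Token tables** (`generate_study_tokens()`) simulate the study design:
3 speakers × 12 consonants (five laryngeal classes) × 2 prosodic
conditions × 7 repetitions = 168 tokens per speaker. Each speaker × class
cell draws its five measures from normal distributions whose means and
SDs default to the published per-speaker summary cells; the per-class
token counts after omission then reproduce the published table counts.
Two generator choices deserve note:

* *Omission.* The published per-consonant counts of unquantifiable
  larynx movements are reproduced exactly by default
  (`omission = "counts"`: that many randomly placed tokens per
  speaker × consonant are flagged); `omission = "bernoulli"` draws each
  token independently with probability count/14 instead. The recorded
  omission counts imply 39 retained voiceless-pulmonic tokens for the
  second speaker where the published table prints 38; we follow the
  omission counts, which only affects that one cell.
* *Larynx duration.* No per-class duration summaries are published, only
  a 200–600 ms range for larynx raising/lowering. Defaults are placed in
  the middle of that range (350–420 ms class means, 70–90 ms SDs) and
  should be treated as assumptions, not estimates. Nasals likewise have
  no published magnitude cells (they are not part of the core contrasts);
  their defaults are mild lowering values chosen for completeness.
* *Lag–duration coupling.* Voiced pulmonic stops show duration-dependent
  lags (onset lags shorten, target lags lengthen with larynx duration),
  while implosive lags are duration-stable. The generator reproduces this
  with per-class correlation coefficients between the lag and duration
  draws (`r_onset = -0.54`, `r_target = +0.54` for voiced pulmonics —
  the mid-point of the published per-consonant correlations — and 0
  elsewhere).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| ROI radius | 3 | px | conventional region size at 2.4 mm pixels (~29 px area) |
| ROI smoothing kernel `h` | 0.9 | frame periods (Gaussian SD) | see below |
| Track smoothing span | 30 | data points (loess, degree 2) | the published smoothing of all gesture signals |
| Landmark threshold | 0.2 | fraction of peak velocity | the conventional 20 % criterion |
| Landmark noise floor | 0.1 | fraction of max \|v\| | rejects quantisation ripple peaks (see below) |
| Segmentation threshold | 0.1 | fraction of VTR robust max | see below |
| Connectivity | 8-connected | — | standard for blob labelling; deterministic row-major component order |
| VTR (larynx) | ~40 mm tall, 10–20 mm wide | mm | must contain the full vertical excursion |

Three of these defaults are genuine design decisions the source method
leaves open, and were fixed by measurement on phantoms:

* **ROI smoothing width.** The ROI literature specifies a locally weighted
  linear regression with kernel width `h = 0.9` without stating the unit.
  Read as a *fraction of the series span* (a loess span), 0.9 — or even
  0.3 — flattens the velocity profile of a 300–400 ms gesture so severely
  that the 20 % landmarks move by tens of milliseconds or disappear,
  which cannot be reconciled with a lag analysis operating at a 12 ms
  frame period. `smooth_weighted_linear()` therefore interprets `h` as
  the standard deviation, in frame periods, of a Gaussian weight for the
  local linear fit (measured onset bias at the default: 1–2 ms), and
  keeps the span-fraction reading available via `h_units = "fraction"`.
* **Segmentation threshold.** How pixels are binarised before connected
  components is unspecified in the source method. The cut is a
  configurable policy (`fraction` of the crop's 99th-percentile
  intensity, `otsu`, or `absolute`). The default fraction 0.1 was chosen
  because the component centroid should approximate the whole-region
  intensity-weighted position (the quantity the technique is named
  after): higher cuts discard the object's intensity skirt, which both
  biases the centroid (≥ 0.12 px at a 0.5 cut on smooth-edged objects,
  versus < 0.05 px at 0.1) and roughly doubles the frame-to-frame
  quantisation ripple of the track, which propagates into
  onset-landmark jitter. At the emulated SNR the 0.1 cut still sits
  ~10 standard deviations above background noise.
* **Landmark noise floor.** "First local maximum of velocity" is fragile:
  even after loess smoothing, tracked phantom velocities carry
  quantisation ripples of 6–8 % of the true peak, so the floor under
  candidate peaks defaults to 10 % of the global absolute velocity
  maximum rather than 5 %.

Other numerical choices: landmark times are sub-frame (linear
interpolation of the velocity between frames — the frame period is coarse
relative to the lag differences of interest); velocities are central
differences (one-sided at the ends); equidistant-component and equal-SD
ties break in row-major pixel order so results are bit-stable; dropout
frames (no supra-threshold component) are flagged invalid and the last
valid centroid remains the continuity reference; the MAX landmark
requires the velocity minimum to fall below the threshold level, so a
monotone drift yields `found = FALSE` rather than a fabricated maximum;
and the ONS crossing uses the *last* sub-threshold crossing before PVEL
(the "first crossing" reading is more noise-sensitive; the choice is
configurable in the source in one place).

Both gesture signals are smoothed before landmark detection: the ROI
series with its local-linear kernel and then, like the centroid track,
with the 30-point local quadratic (loess) smoother. Smoothing biases
ONS-type landmarks slightly early and TONS-type slightly late; applying
the same final smoother to both signals keeps those biases largely
common-mode in the lag measures. On the 20-point recovery grid the
residual lag errors stay under ~10 ms, within one frame period.

## Statistical layer

Variability comparisons use the median-based Levene test
(`brown_forsythe()`): a one-way ANOVA on |x − group median| with
(k − 1, N − k) degrees of freedom, computed directly and verified in the
tests against an independent two-step oracle (explicit transform + textbook
ANOVA, and the car implementation) to machine precision. Group summaries
(`group_summary()`) report speaker × class cells plus a Total row whose
mean is the count-weighted mean of the cells (`pooled_weighted_mean()`);
the Total SD is that of the pooled sample (the alternative — combining
printed cell SDs — is not what the Total row of a descriptive table
usually shows, and only Total means are checked against published
values). Table-style rounding uses half-up (`round_half_up()`), matching
how such tables are typeset.

Equality of coefficients of variation is tested with a profile
likelihood-ratio test under normal models (`cv_equality_test()`): under
the common-CV null the group means are profiled out in closed form
(`n*tau^2*mu^2 + S1*mu − S2 = 0`) and the common CV by 1-D optimisation;
the statistic is referred to chi-square(k − 1), with a parametric
bootstrap (`p_method = "simulation"`) for small samples. The source
literature names a small-sample-modified signed-root variant but prints
no formulas, so calibration is the contract here: measured type-I error
at n = 80 per group over 2000 simulations is ~0.05, and power for CV 0.5
vs 1.5 at n = 80 is ~1. Groups with means numerically indistinguishable
from zero are excluded with a warning (their CV is undefined), and
negative-mean groups are reflected.

Mixed-effects models are deliberately *delegated*: `mixed_model_contract()`
wraps lmerTest/lme4 (random intercepts for speaker, item, and prosodic
condition; Kenward–Roger or Satterthwaite denominator df) and reports the
fixed-effect F, df, p, and a singular-fit flag. Re-implementing REML or
Kenward–Roger is out of scope by design.

## Problem sizes

The shipped tests and the acceptance script use phantom videos of about
100–130 frames (1.2–1.6 s), a 20-point end-to-end parameter grid with
transitions of 360–480 ms and amplitudes of 4–5.5 mm, 2000-replicate
calibration runs for the variance and CV tests at n = 80 per group, and
200 replicate simulated studies for the variance-ordering check. These
sizes give Monte-Carlo error comfortably below the decision margins while
keeping a full run in the tens of seconds.

## Known limitations

* The phantom world is far cleaner than scanner data; real use would
  start from reconstructed magnitude videos plus per-speaker VTR/ROI/seed
  configuration, and the segmentation default may need adjusting per SNR.
* ROI placement is configuration-driven here; the original technique
  places regions manually on anatomy, and no automatic anatomical
  labelling (LAB/COR/DOR) is attempted.
* The landmark logic assumes one gesture per analysed window. Running it
  on long multi-token series requires windowing per token first.
* For ejective fricatives (no full oral closure) the TONS definition is
  applied unchanged to the ROI series; whether that matches the original
  analysis of those segments is unknowable from the published method.
* The CV test's chi-square reference is asymptotic; for groups under
  ~20 observations use the bootstrap p-value.
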