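---
title: "Validating markerless hand tracking against marker-based capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless hand tracking against marker-based capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handkin)
```

## The measurement problem

Markerless hand trackers estimate finger joint-centre positions from stereo
vision and are attractive for clinical use: no markers, low cost, minimal
setup. Before such a device can replace a marker-based optical system for
measuring finger kinematics, the two must be shown to agree on the
quantities clinicians care about — joint flexion angles and their range of
motion (ROM) — under a synchronised, paired protocol. Two practical
obstacles make this comparison non-trivial:

* the reference system samples at a constant rate (150 Hz here) while the
  markerless stream arrives at a *variable* rate around a nominal 120 Hz,
  with occasional dropped frames, so the streams must be rebuilt onto a
  common uniform timeline before any frame-wise comparison;
* each system measures with its own error structure: broadband positional
  noise on every landmark, and — for the markerless tracker — systematic,
  joint-dependent angular offsets (distal joints tend to under-read,
  metacarpophalangeal joints to over-read).

`handkin` implements the complete comparison pipeline, and a synthetic
study generator with known ground truth so that every pipeline stage is
verifiable without capture hardware.

## The hand model

The skeleton is a wrist landmark plus five finger chains. Non-thumb fingers
carry a metacarpal base, MCP, PIP and DIP joint centres, and the fingertip;
the thumb has one bone fewer (metacarpal, proximal and distal phalanges)
and so carries CMC, MCP and IP joint centres and the tip. Joint angles are
three-point angles along a chain $a \to b \to c$:

$$\theta = \arccos\left(\frac{(b-a)\cdot(c-b)}{\lVert b-a\rVert\,\lVert c-b\rVert}\right),$$

so a straight chain reads 0°, and the value always lies in $[0°, 180°]$.
The MCP angle uses (wrist, MCP, PIP), the PIP angle (MCP, PIP, DIP), the
DIP angle (PIP, DIP, tip), and the thumb chain is treated analogously.
This deviation-from-straight convention is taken as the flexion angle
directly (no 180° complement), consistent with flexion minima near zero in
published recordings. The arccos argument is clamped to $[-1, 1]$ to guard
floating-point overshoot on near-collinear points, which limits the
recoverable angle at an exactly straight chain to about $10^{-6}$ degrees —
the accuracy floor of `acos` near 1, not a modelling error.

`forwardPose()` is the inverse map used by the simulator: given segment
lengths and joint angles it places every landmark in 3D. Design choices,
made once:

* **Planar flexion.** No published three-point angle convention defines 3D
  joint axes, so each finger flexes in a fixed sagittal plane containing
  its metacarpal direction; flexion is a rotation about the local
  transverse axis. This makes the forward map exactly consistent with the
  angle equations: recomputing angles from a rendered pose reproduces the
  inputs to $<10^{-9}$ degrees (a property the test suite enforces).
* **Thumb abduction** is a rotation of the whole thumb chain within the
  palm plane about the wrist. It therefore leaves the thumb's three-point
  flexion angles unchanged, and is recovered (in the device frame only) as
  the azimuth of the wrist-to-CMC direction.
* **Metacarpal bases** of the non-thumb fingers sit on a fixed fan from the
  wrist. Their placement does not influence the MCP/PIP/DIP angles, which
  use only the wrist and the finger's own joint centres.
* **Units** are millimetres and degrees throughout, matching how such
  studies report results.

Default segment lengths, and the population norms used to randomise
per-subject skeletons, follow published marker-based group means for ten
adults. Marker-based protocols do not usually instrument the non-thumb
metacarpals, so those four defaults (index 65, middle 62, ring 55, pinky
50 mm) are field-typical anatomical values instead. Per-subject draws are
independent normals truncated at 1 mm so lengths stay strictly positive.

## The synthetic study generator

`generateStudy()` emulates the shape of a paired-systems validation
protocol: by default 10 subjects × 2 trials × 6 movement tasks
(flexion/extension of each finger, thumb flexion, thumb
abduction/adduction) = 120 dynamic trials, plus one static trial per
subject for segment-length estimation. Each movement cycle is a raised
cosine from the rest angle to the peak and back — smooth, starting and
ending at rest, with exactly one maximum per cycle — performed three times
per trial; movement speed is not fixed, so each trial draws a uniform
speed multiplier in [0.8, 1.25].

`renderStream()` simulates one system observing the truth:

* **Frame times.** Inter-frame intervals have mean `1/nominalRate`. With
  jitter CV 0 they are exactly constant (the reference system); otherwise
  they are gamma distributed with the requested coefficient of variation —
  a deliberately simple strictly-positive interval law, since published
  accounts say only that the markerless rate "varies". Trial start and end
  are synchronised programmatically across systems, so both streams open
  at $t=0$ and close with a frame at the trial end.
* **Angular bias.** A per-joint additive offset applied to the true angles
  before rendering, clamped into the physical range. Signs of the default
  test-sensor bias follow the reported error structure (MCP over-reads,
  PIP/DIP under-read).
* **Positional noise.** Isotropic Gaussian noise per landmark coordinate
  (default 0.15 mm reference, 0.5 mm test). Published sources do not
  quantify markerless noise magnitudes; these defaults are *model
  placeholders tuned so that the pipeline-validation invariants are
  informative*, not claims about any device.
* **Dropout.** Frames dropped independently (default 2% for the test
  stream); dropped frames are simply absent rows, never NA padding, and
  frame times remain strictly increasing.

Each bundle derives independent sub-seeds for intervals, noise and dropout
from its own seed, so components are independently reproducible and the
whole study is bit-deterministic given the base seed.

What the generator does **not** emulate: soft tissue and skin-marker
offsets, anatomically accurate rotation axes, occlusion geometry, infrared
interference between systems, or the proprietary skeletal model by which a
real markerless tracker infers joint centres (its systematic error enters
only as the configurable angular bias). Passing tests therefore demonstrate
that the *pipeline* is correct and unbiased under a known error model —
they do not certify any physical device.

## Timeline reconstruction and resampling

For a variable-rate stream the time vector is rebuilt from the inter-frame
intervals: with timestamps present the intervals are their successive
differences (timestamps are strictly more informative than a reported
rate, and the chosen path is recorded in the timeline's `source` field);
otherwise the intervals are reciprocals of the device-reported
instantaneous rates. The rebuilt vector is the cumulative interval sum
with a leading 0, so total duration telescopes to last-minus-first
timestamp exactly.

`resampleUniform()` then interpolates every coordinate linearly onto a
uniform grid at the target rate (150 Hz by default, matching the reference
system). Linear interpolation is chosen over splines deliberately: it is
robust to interval jitter, exact on linear signals, and its error bound is
testable in closed form (a 1 Hz sinusoid of amplitude 45 sampled at a mean
60 Hz with CV 0.2 resamples with RMSE well under 0.1). The grid never
extends beyond the source span — truncation, never extrapolation. Gaps
longer than five nominal intervals are reported as warnings but not
interpolated differently: dropped frames are simply absent before
interpolation.

Trials performed at different speeds are compared after time
normalisation onto a 0–100% grid; 101 points is the biomechanics
convention. Endpoints are preserved exactly and the operation is
idempotent.

`smoothRecording()` optionally applies a zero-lag 4th-order Butterworth
low-pass (default 10 Hz) to uniformly resampled recordings — the standard
treatment of marker trajectories before angle computation. It is
implemented as the filter's magnitude-squared response applied in the
frequency domain after odd-reflection padding, which is the
frequency-domain equivalent of forward–backward filtering, agrees with it
to ~$10^{-4}$ mm away from the edges, and filters all 75 coordinate
columns in two FFTs. It is off by default in `pipelineConfig()` so that
noiseless round-trip identities hold exactly; the bias-recovery validation
(below) turns it on.

## Agreement analysis

For paired per-trial measurements $(x_i, y_i)$ — reference system first —
the Bland–Altman quantities are the differences $d_i = x_i - y_i$ and
means $m_i = (x_i+y_i)/2$; the bias $\bar d$; the limits of agreement
$\bar d \pm 1.96\,s_d$ (the large-sample 95% convention); the bias CI
$\bar d \pm t_{0.975,n-1}\, s_d/\sqrt n$; and a proportional-bias test via
the Pearson correlation of $(m_i, d_i)$, two-sided, $t$-transform with
$n-2$ df, declared at $p < \alpha$ (strict inequality, default
$\alpha = 0.05$, no multiple-testing correction). Constant differences
leave $r$ undefined; it is reported as NaN with a flag, never as 0. The
difference sign convention is reference-minus-test throughout (positive =
test system under-measures), configurable globally.

Design decisions in the study-level tables:

* **ROM pooling.** Published tables rarely state whether per-joint ROM is
  pooled across trials by mean, median, or a pooled max-minus-min; the
  rule is configurable (`poolingRule`), defaulting to the mean of
  per-trial ROMs.
* **One point per trial.** Each Bland–Altman point is one trial's metric
  pair, not a per-subject mean, and no repeated-measures correction is
  applied — matching the simple Bland–Altman analyses such validation
  studies report. Reproducing any particular published per-joint bias or
  correlation would require that study's raw capture data and its
  (unstated) per-plot sample sizes, so the package validates its agreement
  machinery against formula oracles and parameter-recovery experiments
  instead.
* **Segment-length reporting.** Across-subject mean ± sd of per-subject
  mean lengths, systems side by side; non-thumb metacarpals are omitted
  for the reference system, mirroring marker-based reporting practice.

### The agreement metric, and why ROM cannot carry a bias check

The per-trial quantity being paired is configurable
(`agreementMetric`): `"rom"` (default, matching published ROM tables),
`"peak"`, or `"mean"` (the mean angle over the two streams' common time
window). The distinction matters for validation: ROM is a max-minus-min,
so a *constant additive* angular bias cancels in it identically — a
pipeline whose test system reads 10° high everywhere will still show zero
ROM bias. The package's injected-bias recovery experiment therefore pairs
the per-trial **mean** angle, which responds one-to-one to an additive
bias, while the default study tables keep the ROM convention.

### Parameter recovery and honest confidence intervals

`recoverInjectedBias()` validates the whole chain: render paired
single-finger trials with a known test-system bias $b$ at one joint, run
timeline rebuild → resampling → smoothing → angle computation → per-trial
mean → Bland–Altman, and check that the estimated bias is $-b$. Three
details make the confidence intervals honest rather than merely the point
estimate:

* **Low-pass filtering before the arccos.** The angle of noisy vectors is
  inflated upward (the arccos is nonlinear, worst near straight
  configurations), and the inflation scales with the per-sample noise
  variance. Unfiltered, this produces a small systematic offset between
  the two systems' mean angles that is negligible against the ±0.5°
  recovery tolerance but *not* against a CI of width ~0.04° at $n = 60$
  trials. Filtering at 10 Hz cuts the per-sample noise variance by ~8×
  while leaving the (sub-1 Hz) movement untouched.
* **An elevated rest angle** (35°, peak 110°) keeps the biased test-stream
  angles well away from 0° even at $b = -20°$, where the arccos inflation
  becomes first-order.
* **A common integration window** for the two systems' trial means removes
  the differential end-truncation that their different frame rates would
  otherwise cause.

With this design the test suite runs 200 replicate studies per bias level
for $b \in \{-20°, -10°, +10°\}$ and checks, recomputing everything at
every run, that the grand-mean estimate lands within 0.5° of $-b$ (in
practice it lands within a few hundredths of a degree) and that the
empirical 95% CI coverage falls in the honest [0.90, 0.99] band.

## Degenerate inputs and numerical conventions

* Zero-length segment vectors raise a degenerate-geometry error naming the
  frame; coincident static landmarks are flagged per segment.
* Fewer than 2 frames cannot form a timeline; non-increasing timestamps
  raise an error naming the first offending index.
* $n < 3$ pairs, or constant differences/means, leave the trend statistic
  undefined and flagged.
* Angles are validated into $[0°, 180°)$ (flexion) and $(-90°, 90°)$
  (abduction) before rendering; biased angles are clamped to the physical
  range.
* All randomness flows from explicit integer seeds, split per purpose;
  derived seeds stay below $2^{31}$.

## Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to make each
check informative while keeping a full run comfortably interactive: oracle
equivalence on ~120 random paired sets ($n \in [3, 50]$); null-pipeline
checks on 24 noise-free bundles across all six tasks; bias recovery on
200 replicates × 60 trials × 3 bias levels of single-finger trials (one
1.2 s cycle each); and the full default study shape (130 bundles) for the
protocol-count check. The acceptance script
(`scripts/acceptance.R`) re-derives the headline quantities at the same
scales in a few seconds.

## Known limitations

* The planar-flexion hand model cannot represent non-thumb
  abduction/adduction, axis obliquity, or out-of-plane coupling; it is a
  vehicle for validating the measurement pipeline, not an anatomical
  model.
* Thumb-abduction recovery is frame-dependent (device coordinates); the
  pipeline's agreement tables for abduction trials therefore compare the
  thumb's three-point flexion angles, as published analyses do.
* The Bland–Altman implementation is the simple two-sided form: no
  regression-based or mixed-effects variants, and no repeatability
  coefficient.
* The generator's noise magnitudes are placeholders (see above); absolute
  agreement numbers from synthetic studies characterise the pipeline, not
  any physical tracker.
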