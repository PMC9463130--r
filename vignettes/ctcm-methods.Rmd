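---
title: "Models and methods behind ctcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcm)
```

This vignette explains the models the package implements, the assumptions
they rest on, the tunable parameters and their defaults, and the places
where a genuine design choice had to be made. It also states what the
synthetic-data generator does and does not emulate, so that it is clear
what a passing test suite does — and does not — say about real recordings.

## The device cycle

The culture device distends a silicone membrane under a 7-mm support ring
with a pneumatic pressure cycle and paces the tissue electrically. The
package models the air-chamber pressure as piecewise raised-cosine
segments: a rise from baseline to peak over the diastolic fraction of the
period, then a fall back over the systolic fraction. No functional form is
prescribed by the device itself; the raised cosine was chosen because it
is C¹-continuous, has exactly one maximum per cycle (which keeps peak
detection unambiguous), and visually matches recorded pressure traces of
such drivers. Defaults (`cycle_params()`): period 1/1.2 s (72 bpm), 40%
systole, 0 → 80 mmHg (140 mmHg for the overstretch regime), sampled at
1 kHz.

Stimulation is scheduled the way the device's data-acquisition loop works:
a threshold on the rising pressure limb. The threshold is derived from the
configured lead time (default 100 ms before systole onset) by evaluating
the waveform at that time, so the scheduler recovers the lead to within
one sample at any sampling rate. With a lead of zero the threshold equals
the peak and the stimulus coincides with the pressure maximum.

## Stretch geometry

The distended membrane is modelled as a spherical cap over the ring
aperture — the simplest axisymmetric shape for a uniformly pressurised
clamped membrane. For aperture radius $a$ and apex height $h$,

$$R = \frac{a^2 + h^2}{2h}, \qquad \theta = \arcsin(a/R),$$

and percent stretch is the arc-over-chord excess of the deflected profile,
$100\,(\theta/\sin\theta - 1)$. This is zero for a flat membrane, strictly
increasing in $h$, and reaches $100(\pi/2 - 1) \approx 57\%$ at the
hemisphere. The inverse (`height_for_stretch()`) is solved by bracketed
bisection on $[0, a]$ to $10^{-6}$ relative accuracy.

Pressure is mapped to apex height through a monotone piecewise-cubic
(Hyman-filtered) interpolant anchored at the device's calibrated operating
points — (0 mmHg, 0 mm), (80 mmHg, 25% stretch) and (140 mmHg, 32%
stretch) — because no continuous calibration curve is available for the
device; the two printed operating points are treated as exact.

Tissue oversizing follows area scaling: oversizing the slice by a fraction
$f$ of the ring area multiplies the cut diameter by $\sqrt{1+f}$
(7 mm → 7.83 mm at $f = 0.25$).

## The synthetic scene

The generator renders what the analysis stages assume: a Lambertian
membrane-mounted tissue, lit by a distant light, viewed top-down in
orthographic projection. Per frame, pressure → apex height (calibration) →
spherical-cap height field → shading $I = \rho\,(\mathbf n \cdot \mathbf
L)$ → additive illumination drift → additive Gaussian sensor noise →
clipping to $[0,1]$. Identical parameters and seed give bit-identical
stacks.

Defaults and why:

* **Light direction** — zenith 51°, the obliquity of the recording rig,
  at 45° azimuth. Obliquity is what makes shading informative about slope;
  the diagonal azimuth gives both surface-gradient components a
  first-order photometric signal, which is the geometry under which the
  reconstruction below is well conditioned.
* **Albedo** — a seeded, band-limited smooth texture at 10% contrast
  around 0.9 inside the ring (heart-slice surfaces are fairly uniform at
  macro scale), dark background (0.08) outside. A perfectly uniform
  albedo would make the intensity-difference movement trace degenerate.
* **Noise** — additive Gaussian, sd 1% of the dynamic range by default,
  a realistic figure for a consumer sensor at video rates.
* **Field of view** — 9 mm across the short image side, so the 7-mm ring
  fits with margin.
* **Projection** — orthographic top-down; the oblique camera of the real
  rig is available only as an affine foreshortening
  (`camera_tilt_deg`), since no perspective correction is documented for
  the recordings the pipeline targets.

What the generator does *not* emulate: perspective and lens distortion,
rolling shutter, specular reflections, non-rigid in-plane tissue motion,
spatially varying illumination, or the fluid meniscus. Tests passing on
this phantom therefore validate the pipeline's numerics and its behaviour
under the stated image-formation model — not robustness to every artefact
of real recordings.

`simulate_trace()` bypasses rendering for speed: the movement signal is
taken proportional to apex height (arbitrary units), with polynomial drift
in normalised time and seeded noise whose sd is expressed as a fraction of
the clean peak-to-peak amplitude.

## The movement-trace pipeline

The trace is the masked mean absolute pixel difference from a reference
frame (frame 1 by default) — sign-free, so both brightening and darkening
count as movement, and invariant to global intensity offsets.

* **Filter** — first-order Butterworth, applied forward and backward
  (zero net phase, so peak timing is preserved; squared single-pass gain
  = 1/2 at the cutoff), with odd-reflection end padding. Default cutoff
  5 Hz ≈ 4× the pacing frequency: removes pixel noise, keeps the waveform.
  The filter-then-detrend order is fixed and logged.
* **Detrend** — least-squares polynomial of order 6 subtracted from the
  signal. Because the fit is linear, any drift that is itself a polynomial
  of order ≤ 6 is annihilated exactly and the oscillatory part passes
  through unchanged.
* **Peaks** — local extrema with topographic prominence at least 30% of
  the global peak-to-peak range, separated by at least 0.4 s (about half a
  period at 72 bpm), with strict peak/valley alternation enforced. Both
  thresholds are exposed in the configuration; the defaults are chosen to
  be robust at the device rhythm.
* **Metrics** — cycle time = mean peak-to-peak interval; contraction =
  peak → next valley (the systolic downstroke); relaxation = valley →
  next peak; amplitude = mean peak-minus-adjacent-valley; peak speeds from
  the central-difference derivative. Extremum indices are re-located on a
  Savitzky-Golay smoothed copy of the trace (order 2, window 7) within ±3
  samples before timing is read off: the diastolic trough of the device
  waveform is flat, so under noise the raw argmin wanders across it with a
  late bias, which the local-polynomial smoothing reduces. A known
  limitation remains: with white noise at 10% of the signal amplitude the
  contraction/relaxation times carry a residual late-valley bias of
  roughly one frame at 30 fps (the property tests bound the mean error
  over noise realisations by one frame period); cycle time is unaffected.

Up/Down frame selection for the strain stage ranks the detected extrema on
the **raw** trace: both the low-pass filter and, on short clips, the
polynomial fit shift the crest of the asymmetric cycle by a frame or two,
while the raw trace peaks at the true most-distended frame.

## Strain analysis

Segmentation is Otsu thresholding on the frame's own intensity range,
keeping the largest connected component with holes filled. It runs on the
**Down** frame: the near-flat tissue there has no shading-darkened rim, so
the threshold recovers the full outline (on the phantom, Up-frame
segmentation loses a rim crescent).

**Shape from shading.** The reconstruction solves the Lambertian
image-irradiance equation $I = (l_z - p\,l_x - q\,l_y)/\sqrt{1+p^2+q^2}$
for the surface gradients $(p, q)$ with a known light direction, by an
iterative linearised scheme: each sweep applies a minimal-norm
Gauss-Newton update of $(p, q)$ towards the photometric constraint and
then projects the gradient field onto the integrable subspace
(Frankot-Chellappa Poisson solve in the Fourier domain). Shadowed pixels
(predicted irradiance ≤ 0) receive no photometric update. Because the
projection is smoothing and biases steep slopes low, a final
projection-free photometric refinement restores local slope magnitudes,
and the returned height field integrates the refined row gradients along
each image row, anchored to the projected surface's row means. The scheme
is deterministic for fixed inputs and iteration counts (defaults: 200
projection sweeps, 40 refinement sweeps) and exact on flat surfaces.
Direct per-pixel Newton iteration on heights, and whole-field Gauss-Newton,
were both evaluated during design and rejected: the former diverges on
this phantom and the latter stalls in a shallow crimped local minimum of
the photometric objective.

Two assumptions are made explicit:

* **Albedo from the Down frame.** Shape from shading assumes unit albedo;
  real tissue is textured, and texture read as slope collapses the strain
  contrast. The pipeline therefore estimates per-pixel albedo from the
  Down frame under a near-planar assumption ($\rho = I_\mathrm{down} /
  l_z$) and divides it out of both frames. Strain is consequently
  measured **relative to the Down configuration treated as planar**; any
  true curvature of the least-distended state is folded into the
  reference. This matches the strain definition, which uses Down as the
  reference state.
* **Shared scale.** Reconstructed heights are relative; Up and Down are
  reconstructed with identical settings so the unknown scale is shared.
  The per-region **percent difference** between stimulated and
  unstimulated recordings is additionally robust to a shared multiplicative
  height bias, which cancels in the ratio.

**Regions and distances.** The mask is divided into ten equal-width bands
perpendicular to its principal axis (image moments; axis sign
canonicalised for reproducibility). A region's surface distance is the
mean, over scan lines along the axis, of the 3-D polyline length
$\sum\sqrt{\Delta xy^2 + \Delta z^2}$ across adjacent in-region pixels —
the in-plane width in the planar limit. Regional strain is
$(S_\mathrm{up} - S_\mathrm{down})/S_\mathrm{down}$. An axisymmetric cap
concentrates strain near the clamped rim and has nearly flat apex bands,
so for stimulated-vs-unstimulated contrasts the package reports the six
**central** bands (regions 3–8) as the moving span, clear of the clamped
rim where segmentation edge effects and the steepest slopes dominate.

`compare_stim()` reports the per-region percent difference of group means
with a paired two-tailed t-test across slices; with identical groups the
difference is 0 everywhere and the statistic is defined as $t = 0$,
$p = 1$.

## Numerical choices and degenerate inputs

* Bisection tolerances: $10^{-12}$ on the stretch inverse's bracket.
* A flat cap ($h = 0$) is handled as the exact limit ($R = \infty$,
  $\theta = 0$, zero stretch, all-zero height field).
* Flat traces yield an empty peak set without error; metrics require at
  least two peaks and one valley and otherwise fail with diagnostic
  counts.
* The Otsu threshold is computed on each frame's own intensity range, so
  segmentation is invariant to adding a constant to the frame.
* Filters pad by odd reflection; polynomial fits use an orthogonal basis
  for conditioning.
* All randomness flows through explicit integer seeds; the albedo texture
  seed is separate from the sensor-noise seed so the same virtual slice
  can be filmed under different noise realisations.

## Problem sizes

The test-suite and reproduction-script sizes are chosen to exercise every
stage at meaningful resolution while staying quick on a laptop: trace
analyses use 10–20 s of 30-fps signal (12–24 cycles); imaging unit tests
use 48–128 px frames; the full stimulated/unstimulated video comparison
runs at 256 × 256 px over 10 s (300 frames), where the whole pipeline —
rendering, tracing, segmentation, two reconstructions per clip, regional
strain — completes in well under a minute.

## Known limitations

* Strain accuracy inherits shape-from-shading's metric weaknesses: steep
  rim slopes are underestimated, more so with more shadowing, so absolute
  per-region strains are biased low even when the stimulated/unstimulated
  contrast is accurate. The outermost bands are least reliable.
* The Down-frame albedo normalisation assumes the least-distended state is
  planar; residual curvature there is invisible to the method.
* Contraction/relaxation timing carries a ≲ 1-frame late-valley bias under
  heavy trace noise (above).
* The generator's orthographic, single-light, Lambertian world is an
  idealisation; none of the pipeline's robustness to violations of that
  model (specularity, oblique perspective, moving illumination) is
  established by the included tests.
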