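---
title: "Methods: spine-curve determination from back-surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine-curve determination from back-surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinescan)
```

## The measurement model

A laser-triangulation profilometer sweeps a light plane along the back of a
standing patient and stores an ordered point cloud: a grid of profiles
(index `v`, one per laser position along the longitudinal translation) by
samples (index `u`, along the profile), each cell carrying `X, Y, Z`
coordinates in mm and a brightness value. `spinescan` adopts the
conventions:

* `X` caudal → cranial along the translation; per-profile mean `X` must be
  strictly monotonic in `v`.
* `Y` lateral, positive toward the patient's left.
* `Z` depth, positive from the back toward the camera. Consequently the
  posterior median furrow — the midline skin depression over the spinous
  processes — is a local *minimum* of `Z` along `Y`, and a concave feature
  has *positive* transverse curvature. This sign convention is load-bearing
  for everything downstream.

Dropouts (laser occlusion) are carried as an explicit validity mask, never
as sentinel coordinates. Brightness lives on `[0, 1]`; integer-scale
brightness (8-bit exports) is min–max normalised at load, because the
intensity thresholds of the manual detector are only meaningful on a
normalised scale.

## Automatic curve: transverse curvature

On each profile the depth graph `Z(Y)` is differentiated and the curvature
of the graph computed as

$$K = \frac{Z''}{\left(1 + Z'^2\right)^{3/2}},$$

using 3-point central finite differences with non-uniform-spacing weights.
This is the simplest scheme that reproduces `K = 1/R` on a circular arc
sampled at the scanner's 1 mm pitch to better than 1 % — the package's
standing accuracy check — and it is exact at the apex of a parabola.

**Depth presmoothing.** Second derivatives amplify the 0.1 mm single-point
sensor noise, so `Z` is smoothed with a 1-D Gaussian before
differentiation. The smoothing scale must sit well above the one-sample
noise correlation length and well below the ~10 mm furrow half-width; the
package default is `presmooth_sigma = 4` samples. Smaller values
demonstrably leave the per-row curvature maximum noise-dominated at the
reference noise level (the furrow track fragments and per-row localisation
jitter reaches a full column), while 4 samples attenuate the apex curvature
of the 10 mm furrow by only a few percent. The parameter is exposed
everywhere; setting it to 0 disables smoothing.

**Run-edge invalidation.** Wherever the Gaussian kernel of a sample extends
past the end of a valid run, its smoothed value depends on data that does
not exist. Renormalising the kernel over the available support — the usual
fallback — fabricates strong spurious curvature at run edges, which in
early experiments dominated per-row detection on a third of the rows. The
curvature map therefore flags the first and last kernel-radius samples of
every valid run invalid (at minimum the run endpoints, which central
differences cannot serve anyway).

**Detection, deduplication, linking.** Per row, every local curvature
maximum strictly above the working threshold of zero is kept — the zero
threshold deliberately retains every concave ridge so that the full
candidate family is available for selection. Each maximum is refined to
sub-pixel position by a least-squares quadratic over a 5-point window
(configurable 3–9; 3 is noise-fragile, 9 blurs double ridges); if the
fitted vertex escapes the window or the parabola opens the wrong way the
discrete extremum is returned and flagged unrefined. Two maxima closer
than the refinement half-window are a single unresolvable feature — noise
can split one peak into twins a fraction of a column apart — so only the
stronger is kept; without this the twin forks a parallel track that then
starves the true one under greedy linking.

Linking itself is greedy and deterministic: walking down the rows, a
detection joins the open candidate whose last position is nearest within
`max_jump = 3` columns (candidates stay open for `max_gap = 5` missing
rows, which are then bridged by linear interpolation and flagged);
candidates shorter than `min_length = 20` rows are dropped. The interactive
workflow's single mouse click becomes an explicit seed point:
`select_curve()` returns the candidate polyline nearest to the seed,
breaking ties by length and then by mean strength, which makes operator
studies scriptable and reproducible.

## Manual curve: the marker line

The physician's pen line is recovered from the brightness channel. The
image is smoothed with a 7×7 Gaussian kernel (σ = 1.5 samples, so the
kernel is effectively supported in 7×7 — the standard truncation at ~2σ)
to suppress the wide, high-contrast marking, then the
global minimum of each row is tested against the intensity cut and refined
to sub-pixel position; rows without an accepted minimum between the first
and last accepted rows are filled by 1-D interpolation, yielding a
continuous curve. The global (rather than any local) minimum is used: the
marker is by construction the darkest object in the region of interest.

**Threshold semantics.** The cut (default 0.10, useful range 0.08–0.15) is
applied to the *dip depth below the row's background level*, estimated as
the row's median smoothed brightness, rather than to absolute brightness.
The reason is structural: smoothing necessarily raises the dip bottom of a
marker of finite contrast (a marker of contrast `c` can never fall below
brightness `1 − c`, and the 7×7 kernel lifts it further), so an absolute
cut near 0.1 silently rejects legitimate markers of contrast ≲ 0.9 — while
on a normalised image whose background sits near 1 the two readings
coincide for near-black markers. The background-relative cut keeps the
0.08–0.15 range meaningful and degrades gracefully with marker contrast; a
faint marker (contrast 0.05, dip depth ≈ 0.04) is still correctly
rejected at the default cut. `detect_rows()`'s generic intensity-min mode
retains the plain absolute comparison for callers that want it.

## Lifting, smoothing, projection

A detected image-space curve has one sub-pixel position per covered row;
`lift_curve()` linearly interpolates `X, Y, Z` between the two grid columns
bracketing it (interpolation is only needed along `u`; `v` is integral by
construction). Rows with an invalid bracketing cell are dropped and
reported.

Smoothing fits least-squares cubic splines with uniform interior knots
independently to `Y(X)` and `Z(X)` — the two anatomical planes are treated
separately throughout — and evaluates them at the original `X` positions.
The default knot spacing of 30 mm resolves the at-most-four anatomical
curvature lobes over a ~500 mm thoraco-lumbar span while suppressing
point noise, and, being a piecewise-cubic least-squares projection, it is
idempotent, reproduces exact cubics, and avoids the end-interval
oscillation of high-degree polynomial fits (Runge's phenomenon) by
construction. Smoothing is performed in 3-D space (on the lifted
coordinates), not in image space. Projection to the frontal (X–Y) or
sagittal (X–Z) plane is pure coordinate selection.

## Comparison and repeatability statistics

The automatic curve is systematically shorter than the manual one — the
furrow fades above the shoulder blades — so curves are compared only over
the intersection of their `X` spans. Both curves are resampled by linear
interpolation at the profile-row `X` grid of the first curve inside that
span, and the RMSD is computed per plane with divisor `n` equal to the
number of common rows (the only reading under which "one difference per
X row" is coherent).

`cohort_summary()` reports mean, SD, median, min and max; the SD uses the
*population* divisor `n`. This convention is not arbitrary: it is the one
under which the packaged per-patient table reproduces its own printed
summary row (4.63 ± 1.48 mm frontal; the sample divisor gives 1.51).
Rounding is left entirely to presentation.

`repeatability()` takes repeated (manual, automatic) curve pairs of one
subject, resamples everything onto the shared span, and computes at each
`X`: the SD across repeats of the manual position (posture variation — the
subject cannot stand identically twice) and the SD across repeats of the
per-repeat manual-minus-automatic difference (method variation — posture
cancels in the difference because both curves come from the same
measurement). The four headline scalars are the means of these SD-vs-X
curves, frontal and sagittal.

`simulate_repeats()` provides the matching generative model at curve
level: a per-row posture deviation field drawn independently at each
profile row and *shared* by the manual and automatic curve of a repeat,
plus independent per-row detection noise on each curve. Two modelling
choices deserve a note. First, the simulation operates on curves, not on
full rendered scans: the experiment's purpose is to validate the
*statistics*, which requires detection noise to be set exactly, not
estimated. Second, posture is sampled per row rather than as a rigid
per-repeat offset: the repeatability statistics have the same expectation
either way, but a rigid offset leaves the posture-SD estimate with only
`n_repeats` effective draws (≈16 % relative sampling error at 20 repeats),
making any recovery check statistically meaningless; real sway is smooth
in `X`, which affects only the (unused) spatial correlation of the per-X
curves.

## The synthetic back

`synthetic_spec()` defines the validation surface:

| parameter | default | meaning |
|---|---|---|
| `n_rows` × `n_cols` | 700 × 300 | grid (≈ 630 × 300 mm field) |
| `profile_spacing_mm` | 0.9 | scanner profile pitch |
| `col_spacing_mm` | 1.0 | sample pitch along the profile |
| `torso_half_width_mm`, `torso_depth_mm` | 170, 50 | elliptic torso section |
| `sagittal_profile` | cubic, ≈ ±11 mm | kyphosis/lordosis double-S `s(X)` |
| `spine_curve` | `40t(1−t)`, max 10 mm | lateral centerline `c(X)` |
| `furrow_depth_mm`, `furrow_halfwidth_mm` | 4, 10 | Gaussian furrow |
| `marker_offset_mm` | 0 | palpation error of the drawn line |
| `marker_halfwidth_mm`, `marker_contrast` | 2.5, 0.8 | marker brightness dip |
| `noise_sd_mm` | 0.1 | Gaussian depth noise (sensor accuracy) |

The surface is the elliptic section plus `s(X)`, carved by the furrow
`−d(X)\,e^{-(Y-c(X))^2/2h^2}`; the furrow depth tapers linearly to 30 % of
its nominal value over the cranial quarter of rows, reproducing the fading
furrow above the shoulder blades that forces a row-direction ROI reduction
on real data. Optional shoulder-blade bumps add convex relief whose
concave flanks spawn additional curvature candidates, as on real backs.
Polynomial coefficient specs are evaluated in `t = X / max(X)`; arbitrary
functions of `t` are accepted. Noise is independent Gaussian on `Z` only,
matching the instrument's stated single-point accuracy while keeping the
generator analytic. Furrow depth and width in millimetres are package
choices (no quantitative furrow morphometry was available to match);
4 mm / 10 mm give a clearly visible but not caricatured crease.

What the generator does **not** emulate: skin-fold and adipose variation,
breathing and sway during the 10 s sweep, marker-width variation along the
line, specular dropouts correlated with geometry, and vertebral axial
rotation (out of scope entirely — surface curves are not X-ray curves).
Passing the synthetic recovery checks therefore shows the algorithmic
chain is correct and noise-robust at instrument-realistic levels; it does
not certify clinical accuracy on real patients.

## Numerical choices and degenerate inputs

* Sub-pixel refinement falls back to the discrete extremum (flagged) when
  the quadratic is degenerate, opens the wrong way, or its vertex leaves
  the window; all-equal windows are an error, not a guess.
* Selection ties (equal distance within 10⁻⁹) go to the longer, then the
  stronger candidate — deterministic by construction; identical inputs
  yield bit-identical curves everywhere (no hidden randomness; the
  generator and the repeat simulator require explicit seeds and restore
  the caller's RNG state).
* Profiles need ≥ 5 contiguous valid samples for curvature; rows below
  that are invalid, a fully invalid ROI is an error.
* Spline smoothing requires ≥ 8 samples and knot spacing above twice the
  sample spacing; rank-deficient fits are handled by the QR path of
  `lm.fit`.
* `rotate_about_x()` resamples each rotated profile back onto its original
  uniform `Y` grid (linear interpolation) so the scan remains a depth
  graph; points leaving the field of view become invalid. Rotation is the
  package's instrument-orientation robustness probe: the curvature of a
  surface curve is geometric, so detection should be — and is, to
  ≈ 0.14 mm RMS at ±5° — insensitive to how the patient is rotated about
  the scan axis.

## Problem sizes used by the test suite

Unit tests run on 150 × 100 synthetic grids; the end-to-end validation
uses the full 700 × 300 reference geometry with five noise seeds for
automatic-curve recovery, one seed for manual recovery, ±5° rotations of a
noise-free scan, and 20-repeat simulated repeatability experiments with
posture SD 2 mm and detection SD 0.4 mm — the same conditions
`scripts/acceptance.R` re-runs from scratch.

## Known limitations

* The greedy linker can still hand a track over between overlapping
  candidates under heavy noise; the seed-point selection then returns one
  segment rather than the union. Coverage of the interior span is asserted
  in the tests precisely to surface such regressions.
* The manual detector assumes one marker line in the ROI (global minimum
  per row); two competing dark lines require ROI narrowing.
* `cohort_summary()` deliberately reports mean, SD, median and max
  side-by-side; which of these a "typical value" refers to is left to the
  analyst.
* Transition marks between spine zones (short horizontal ticks some
  protocols draw) are not detected or used.
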