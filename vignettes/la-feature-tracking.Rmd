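---
title: "Left atrial feature tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial feature tracking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model behind `latrack`, the
choices that were genuinely open when it was built, and what the synthetic
phantom can and cannot tell you about performance on real data.

## The measurement chain

The left atrium (LA) is quantified from long-axis cine CMR in five steps.

1. **Reference contour.** An open endocardial polyline is drawn at the
   ventricular end-systolic frame — the frame just before mitral valve
   opening, when the LA is largest — running from one mitral-annulus
   anchor to the other. The pulmonary-vein confluence and the LA appendage
   are excluded by convention. Before tracking, the polyline is resampled
   to ~2 mm equal arc-length spacing (endpoints preserved) so every patch
   covers the wall uniformly; the point count is then fixed for the whole
   cycle so arc lengths are comparable across frames.

2. **Propagation.** Each point carries a square intensity template
   (default 10 × 10 mm) that is matched into the next frame by
   zero-normalized cross-correlation (ZNCC) over integer displacements
   within a search radius (default 5 mm per 35 ms frame pair — comfortably
   above the wall excursion of a normal atrium at that temporal
   resolution), followed by a 1-D parabolic subpixel fit per axis.
   Matching is strictly frame-to-frame with the template resampled at each
   frame's tracked position, forward from the reference frame and wrapping
   through the last frame back toward it.

3. **Volumes.** Per frame, the polyline is closed with the straight
   annulus chord; the shoelace area and the chord-midpoint-to-roof length
   of the two views enter the biplane area–length formula
   `V = 0.848 A4 A2 / ((L2 + L4)/2)` (mm³ → ml). The constant 0.848 is the
   conventional rounding of 8/(3π) ≈ 0.84883, which is why the formula
   reproduces an exact ellipsoid volume only to within 0.15%. Short-axis
   stacks use Simpson's rule of disks, `Σ areas × (thickness + gap)`, with
   the protocol's 8 mm slices and 2 mm gaps.

4. **Phases and ejection fractions.** `i_max` is the volume argmax.
   `i_min` is the argmin *after* `i_max` in displayed-cycle order: the
   physiological V~min~ is reached at the end of active emptying, just
   before mitral valve closure, while the first frames of the displayed
   cycle may still sit at the previous cycle's minimum level, so a global
   argmin would be ambiguous there. V~preA~ is the volume at the
   conduit-to-booster transition; it is detected where the volume change
   is closest to zero within the diastolic window, or taken at the ECG
   P-wave frame when one is supplied. LAEF, LAPEF and LAAEF follow from
   the three volumes and satisfy the identity
   `LAEF = LAPEF + LAAEF · VpreA/Vmax` exactly.

5. **Strain.** Per view, global longitudinal strain is the fractional
   change of endocardial arc length; the global curve is the unweighted
   mean of the two views (the usual biplane convention when no weighting
   is specified). The strain rate is the cyclic central difference in
   %/ms. S~max~ is the curve maximum; SR~max~ the strain-rate maximum on
   the filling interval; SR~e~ and SR~a~ the most negative strain rates in
   the conduit and booster intervals.

## Design decisions

**Strain reference frame.** Contours are *drawn* at ventricular
end-systole, but strain is *referenced* to the minimum-volume frame
(ventricular end-diastole). The two choices are independent; referencing
to the minimum makes the reservoir peak positive, matching the convention
in which S~max~ is reported as a positive "peak global longitudinal
strain" in the low twenties of percent. Referencing to the drawing frame
would shift the whole curve down by a constant factor without changing
the physiology.

**V~preA~ detection on backward differences.** The "volume change closest
to zero" rule is implemented on the backward difference V(t) − V(t−1),
not on the central-difference rate. On a plateau of constant volume the
central difference is zero one frame *before* the plateau ends, whereas
the backward difference is zero up to and including the last plateau
frame — and it is the last frame before the volume starts dropping that
marks the onset of atrial contraction. Near-ties are resolved to the
*latest* frame within a tolerance of 10% of the in-window |ΔV| range, so
an exact diastasis plateau and a noisily tracked one both resolve to the
plateau's final frame. The window itself starts after the early-emptying
rate minimum (located on the central-difference rate) and ends at `i_min`
(exclusive) or at the P-wave frame (inclusive) when given. The detection
is invariant to adding a constant to the volume curve and to uniform time
rescaling.

**Tracker internals.** The commercial feature-tracking products do not
document their matching internals, so the following are this package's own
choices, each a standard component of speckle/feature tracking:

* *Gaussian-weighted ZNCC* (σ = patch/4). The wall texture lies on one
  side of an endocardial point; with uniform weighting the correlation
  latches onto the texture centroid, which under chamber contraction moves
  farther than the boundary point itself. Centre weighting anchors the
  estimate at the point while the full 10 mm patch still supplies texture.
* *Symmetric matching.* The pattern deforms slightly between frames, which
  shifts the correlation peak by a small bias whose sign follows the
  matching direction; matching forward, then matching the displaced point
  backward and averaging cancels the bias to first order. Because the
  deformation is monotone over each phase, this bias would otherwise
  accumulate coherently over the cycle.
* *Displacement smoothing along the contour* (binomial window of 5
  points ≈ 8 mm). Neighbouring wall points move almost identically within
  35 ms; smoothing the per-step displacement field suppresses independent
  match jitter that would otherwise make the polyline jagged and inflate
  its arc length (and hence strain).
* *Cyclic drift compensation.* After the full wrap the residual between
  the re-entered and the original reference contour is distributed
  linearly over the cycle, so the frames tracked last do not carry the
  whole accumulated error. The reported closure drift is always the raw,
  uncorrected residual — it remains the honest diagnostic of tracking
  quality.
* *Determinism.* Exact ZNCC ties are broken by the smallest displacement
  magnitude, then row-major order. Zero-variance (flat) templates score 0,
  are flagged, and inherit the mean displacement of the remaining points,
  so featureless segments cannot inject NaNs or spurious motion.
* *Borders.* Templates partially outside the image are cropped
  symmetrically and flagged; a point outside the image is an error.

**Statistics conventions.** The ICC is the two-way random, single-measures,
absolute-agreement form ICC(2,1) — appropriate for two raters or visits
with single measurements — with the consistency form available as an
option. Passing–Bablok uses the 1983 shifted-median estimator with the
rank-based analytic confidence bounds (no bootstrap, so results are
deterministic); pairwise slopes of exactly −1 are discarded and vertical
pairs excluded, per the original definition. The SEM is computed from the
SD of the paired test–retest differences by default — the convention under
which published reliability tables of this kind reproduce — with the
pooled-measurement SD as an option. The SDC is computed from the
full-precision SEM; a `round_sem` option reproduces reports in which the
SEM was rounded to two decimals first (published tables are not consistent
on this point, and neither convention reproduces every printed row).
Pearson grades use closed upper bounds ("0.01–0.20" includes 0.20).

## The phantom

The phantom emulates an SSFP-like cine acquisition of a tri-phasically
deforming LA: 30 frames at 35 ms, 1 mm pixels, a 40 × 25 × 20 mm ellipsoid
chamber (V~max~ 83.78 ml) with a dark cavity and a bright wall carrying
band-limited speckle. The volume curve is built from cosine segments —
reservoir filling to frame 11, conduit emptying to a diastasis plateau
(frames 18–24), then booster emptying to the minimum at frame 30 — with
V~min~ = 0.54 V~max~ and V~preA~ = 0.82 V~max~, i.e. LAEF 46% and LAPEF
18%, typical biplane feature-tracking values; the P-wave frame is defined
as the plateau end. Deformation is an isotropic in-plane scaling about the
annulus midpoint with s(t) = (V(t)/V~max~)^(1/3), which keeps the
ground-truth strain available in closed form, (s(t)/s~min~ − 1)·100
(S~max~ ≈ 22.8%). The speckle is a sum of random plane-wave cosines
generated once in reference coordinates and evaluated analytically at the
warped positions, so the wall pattern is advected exactly, without
interpolation error, and tracking must succeed by texture rather than by
the edge alone. Tissue interfaces get a ~0.4 mm logistic partial-volume
transition — hard binary edges alias and systematically bias subpixel
matching, and real SSFP data are band-limited anyway. Gaussian intensity
noise (SD 5 against a wall texture amplitude of 45) is drawn fresh per
frame; the whole phantom is bit-reproducible from its seed.

What the phantom does *not* model: MR physics (no SSFP banding, coil
profiles or flow artifacts), pulmonary veins and appendage (excluded from
the segmentation convention anyway), through-plane motion, non-affine
regional deformation, and arrhythmic cycle-length variation. Passing the
phantom suite therefore demonstrates that the chain is implemented
correctly and is accurate under smooth, in-plane, texture-preserving
motion — it does not certify accuracy on patient data, where tracking
quality must still be reviewed (the per-frame score report and the raw
closure drift exist for exactly that purpose).

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the full chain on the default
30-frame, 128 × 128 px phantom (two views, ~100 contour points each, which
tracks in well under a minute on one CPU); oracle equivalences use 100
random datasets of up to 50 pairs (Passing–Bablok, exact equality) and 100
random two-rater tables (ICC, 10⁻¹⁰); the simulated two-visit reliability
study uses n = 500 subjects with a designed ICC of 0.82. Volume curves
require a uniform frame interval (the protocol's), at least 4 frames, and
a non-monotone cycle; ejection fractions enforce
V~max~ ≥ V~preA~ ≥ V~min~ > 0 and name the violated inequality otherwise.

```{r example}
library(latrack)
ph  <- make_phantom(phantom_config())
gt  <- ph$ground_truth
ref <- gt$phase_indices$i_max
fit <- la_analyze(ph$cine_2ch, ph$cine_4ch,
                  gt$contours_2ch[[ref]], gt$contours_4ch[[ref]],
                  ref_frame = ref)
summary(fit)
plot(fit)
```

## Known limitations

* Only the endocardial layer is tracked; no epicardial contour, hence no
  wall-thickness or radial/circumferential strain.
* Global strain only; no regional (segmental) strain maps.
* The biplane method itself underestimates volumes when the LA shape is
  distorted or the long-axis planes are misaligned — a property of the
  formula, not of this implementation; Simpson's method is provided for
  short-axis stacks.
* DICOM ingestion is out of scope; images enter as NIfTI or multi-page
  TIFF with explicit spacing/timing metadata (missing metadata is an
  error, never a silent default).
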