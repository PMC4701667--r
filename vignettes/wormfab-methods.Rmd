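---
title: "wormfab: models, design rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormfab: models, design rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormfab)
```

wormfab is a workbench for *dynamically photopatterned* C. elegans assays:
hydrogel (PEG-DA) microstructures are cured directly on an NGM culture plate
by projecting binary masks through a microscope objective with a digital
micromirror device (DMD), while the animal is watched by a camera through
the same optics. The package covers the computational side of such a rig —
mask compilation, exposure/resolution design rules, video tracking, assay
statistics and the closed-loop observe→decide→pattern cycle — and ships a
ground-truthed synthetic worm-video simulator so everything can be exercised
and validated without hardware.

This vignette records the models and the deliberate numerical choices; it
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## Coordinates and masks

World coordinates are micrometres, y-up, origin at the centre of the
projected field; images and masks are 1-based `[row, col]` matrices, y-down,
with pixel-centre sampling. (R is 1-based throughout; using 0-based DMD
indices would force an off-by-one at every matrix access, so the pixel
convention is 1-based and stated once here.) `projection_transform()` maps
between the two; round-trip error is at machine precision.

A mask pixel is ON iff its centre lies inside the pattern's *solid* —
for confinement geometries the wall or pillar material, never the lumen.
There is no anti-aliasing: a DMD mirror is binary. Softening of edges in the
cured hydrogel is modelled separately (below). Pattern containment tests are
analytic per primitive (rectangle algebra, lattice folding for pillar
arrays, distance-to-lumen for the T-maze, winding-arm distance for the
spiral, ray casting for polygons), which makes rasterization exactly
reproducible: identical `(spec, transform)` gives bit-identical bitmaps.

Multi-exposure stitching (`stitch()`) is a union in world coordinates —
idempotent, commutative, associative — because exposing cured gel again
cures nothing new.

## Exposure and resolution design rules

The calibration table ships only the text-anchored resolution values:
~3 um (50X) and ~23 um (5X) for thick 10–100 um films, 0.7 um (50X) and
1 um (20X) for 1 um films. Figure-derived anchors are deliberately not
encoded (not readable with confidence); users can extend the table from a
config file. Lookup is log-log linear within an objective's anchored height
range and clamps (with a warning) outside it.

Optimal exposure follows the empirical *inverse* exposure–height
relationship (oxygen diffusing through the NGM inhibits polymerization at
the interface, so thin films cure slower). With fewer than two exposure
anchors the parametric fallback `t = k/h` is used; `k = 100 s·um` so that a
100 um tall feature takes 1 s, matching the frame exposure used in the
confinement experiment. Exposures never drop below the 50 ms mechanical
shutter limit.

Design rules enforced by `validate_feature()`:

* raised solids narrower than **50 um** break off the agar on rinsing
  (adhesion failure) — applied to all raised solids, as the narrowest
  printed statement covers only the minimum feature;
* negative channels narrower than the line-pair resolution at the working
  height are unresolvable;
* features taller than the bead-defined cover gap are impossible;
* `adhesion_check()` is a strict 300 s threshold: five minutes of PEG-DA
  diffusion into the agar before exposure, otherwise no bond.

The ~2:1 height:width aspect observed at the minimum feature size is kept as
a table constant but not enforced as a reject rule — it is a property of the
minimum, not a general constraint.

## The optical blur dose model

A single isotropic Gaussian kernel per objective stands in for the entire
projection optics; thresholding the blurred mask at 0.5 predicts the cured
footprint. The 5X kernel width is a one-time derived calibration: solving
for the sigma at which the shipped corner-fitting procedure returns a 10 um
radius on a right-angle wall corner gives `sigma = 6.277 um`; other
objectives scale as 1/magnification. The corner fit collects sub-pixel
0.5-crossings around the corner, keeps points deviating from both ideal
edges by more than 0.15 sigma within 3 sigma of the corner, and fits a Kasa
least-squares circle. A straight edge's 0.5-crossing stays on the ideal
edge by symmetry, so the model only rounds corners — it does not move walls.

## The synthetic worm

The simulator is a *stated world*, not a fit: it exists to exercise the
tracker and the closed loop with known ground truth.

* **Kinematics, not dynamics.** The head advances along its heading at a
  prescribed speed; the spine follows the head's past path
  (follow-the-leader); a travelling sinusoidal wave is superimposed
  perpendicular to the spine. No forces, no fluid.
* **Gait defaults**: body 1000 x 60 um (adult), wavelength one body length
  and frequency 2 Hz (adult swimming gait), amplitude 120 um clipped
  automatically to the available clearance (minimum clearance along the
  body plus a 300 um lookahead; the amplitude shrinks instantly and
  regrows slowly, so the body never swings into a wall).
* **Centre-of-mass conservation.** The shape wave is made zero-mean across
  the body each instant, so the body centroid stays on the smooth spine
  path. The prescribed translation already encodes the net effect of
  propulsion; letting the shape wave also translate the centroid would
  double-count it and make "centroid speed" ambiguous. With the wavelength
  an integer fraction of the body length this correction is small.
* **Wave speed sanity**: frequency x wavelength = 2 mm/s, well above every
  simulated translation speed — the large-slip regime of real undulatory
  swimming. (If translation approached the wave speed the rendered body
  would look frozen between frames and frame differencing would see only
  head and tail.)
* **Speed profile**: per-stage peak speed is a direct parameter, applied
  with a plateaued modulation `min(1, 0.35 + 0.85 sin^2(pi t / 30 s))` — a
  deterministic burst-and-glide pattern whose plateaus make the maximum
  speed well defined. The confinement–speed coupling is also available as
  a clearance-dependent gain for free-roaming worms.
* **Collisions** are resolved by steering: candidate headings are scanned
  outward from the intended one and the first with enough clearance for
  half the body width plus the current undulation amplitude wins; a boxed-in
  worm reverses. Channel and maze worms are path-constrained (they move
  along the lumen centreline and bounce at its ends), which keeps their
  speed exactly prescribed. On a curved path the arc advance is compensated
  by the mean-body-tangent factor so that the *centroid* — the observable a
  tracker reports — moves at the prescribed speed.
* **Camera**: 5 um/px, 10 fps, background 200, worm 60, cured gel 150,
  additive Gaussian noise sd 3 gray levels, 8-bit quantization. Values are
  nominal for a consumer SLR watching a dark worm on bright agar.

What the simulator does **not** emulate: posture-realistic gait changes
(omega turns, reversals as behavioural states), anatomy (the body is a
constant-width tube), illumination gradients, partially cured "leaky" walls
(available only as an explicit flag), or multi-worm interactions. A green
test therefore establishes that the *pipeline* is correct on a worm-like
moving object — not that any biological claim generalises.

The T-maze scenario seeds a left/right choice (probability configurable,
0.5 by default), drives the worm along the maze lumen and coils it inside
the chosen terminal disc, mirroring how a real worm's body accumulates in
the terminal region until the 80%-body rule fires.

## Tracking pipeline

Frame differencing → blob detection → worm selection → centroid →
kinematics, with every threshold the original method description leaves
open exposed in `tracker_config()`:

* differencing threshold: Otsu on the absolute-difference histogram.
  Otsu collapses into the noise mode when the mover covers a tiny pixel
  fraction, so the threshold is floored at 5x the MAD-estimated difference
  noise sigma (and never below 5 gray levels);
* speckle removal: opening with the 3x3 square element (the OpenCV
  default structuring element). Under pure noise (sd 3) fewer than 0.1% of
  pixels survive;
* **closing** (radius 15 px): an undulating worm's frame difference
  fragments into one patch per half body wave; closing re-merges them into
  a single blob. The radius must exceed the internode gap (about a quarter
  wavelength in pixels);
* blob selection: largest blob initially, nearest-to-previous within a
  2 x body-length gate afterwards; no qualifying blob flags the frame
  invalid and carries the last position;
* **body refinement**: the motion blob *locates* the worm; the reported
  centroid is the dark-body segmentation centroid around it (median
  background of the first 10 frames, then a running-max update that erases
  the worm's own ghost once it swims away). The body centre of mass is
  stable in the body frame, whereas the raw motion-blob centroid wanders
  with pose — the head sweeps more area than the tail. The segmentation
  window is padded by about one body length, because a straight
  wall-gliding worm's frame difference shrinks to its head and tail caps;
* kinematics: a 5-point rolling median (despiking 1–2-frame association
  glitches), then a cascade of period-matched moving averages (windows 5,
  7, 9 frames at 10 fps: exact nulls at 2 and 4 Hz and a deep stop band
  across the gait sidebands that turning modulation produces), then a local
  quadratic (Savitzky–Golay) fit, window 5; velocity and acceleration by
  central differences of the smoothed positions, one-sided at run ends.
  Frames whose filter support is truncated at a run boundary are flagged
  `full_support = FALSE` and excluded from summary statistics — boundary
  estimates mix shrunken windows with one-sided differences and are
  known-biased.

Orientation is the principal axis of the second central moments, reported
in degrees from vertical (clockwise positive) in `(-90, 90]`, unwrapped
over time to remove 180-degree flips. On a rendered lever following the
6°→27° push-cycle schedule the tracker recovers the schedule to a fraction
of a degree (see `hinge_replay()` and the acceptance suite).

Speed summaries use linear-interpolation quartiles (R type 7), and the
"maximum speed" of a configuration is the maximum of the smoothed speed
over valid, full-support frames. The percent-of-baseline convention is the
ratio of maxima: 890/330 um/s reads as ~270%.

## Assay statistics

* **Maze outcomes**: first frame with >= 80% of body pixels inside a
  terminal disc decides LEFT/RIGHT (strict threshold: 79% forever is
  INCOMPLETE). Escape — the worm climbing out — is operationalized as body
  pixels touching the image border or sitting further than 100 um from the
  maze lumen for 5 consecutive frames; escapers are excluded from the
  choice test, never refilled into the maze.
* **Choice test**: exact two-sided binomial (sum of outcome probabilities
  not exceeding the observed one) with a Clopper–Pearson interval. Note a
  discreteness fact the test suite pins down: at n = 38 the attainable size
  of the exact test at nominal alpha 0.05 is 0.0335 (rejection at k <= 12
  or k >= 26), the closest achievable level below 0.05.
* **Survival**: product-limit (Kaplan–Meier) estimator with censored worms
  (internally hatched eggs, desiccation, extruded gonad, edge crawling) at
  risk through their censor day; median lifespan is the first day with
  S <= 0.5; a two-group log-rank chi-square (1 df) is included. The
  implementation is self-contained and is tested against both a
  hand-computed table and the `survival` package as independent oracle.

## The closed loop

`run_experiment()` couples the tracker's output (not the simulator's ground
truth — the loop observes what a real rig would observe) to trigger rules:
`at_time`, `worm_in_region` (dwell-gated), or `manual` events. Actions are
validated against the fabrication design rules before scheduling; rejected
exposures are logged. Cured geometry becomes collidable only at
`cure_complete = exposure_start + exposure_time + ~1 s` of
photopolymerization, and a worm overlapping a footprint at cure time is
relocated to the nearest free lumen with a freshly built body lane — never
embedded in gel. Uncured regions stay freely swimmable (rinsing is only
possible on worm-free plates). Logs are replayable: a seed reproduces the
run bit for bit.

The freehand path (`stroke_stream()` → `stroke_to_mask_updates()` →
`freehand_session()`) scales tablet input by a single end-to-end 50x fold,
delays each stamp by the 250 ms touch-to-projection latency, joins
fast-stroke subsampling gaps (consecutive events closer than 0.2 s but
further apart than one brush radius) with stamped segments, and treats
separate taps as separate discs.

## Known limitations

* The exposure table degrades to the `k/h` fallback outside its anchors; it
  is a design aid, not a photochemistry model.
* The blur model is a single Gaussian: no diffraction rings, no defocus
  asymmetry, no illumination falloff (the experimentally observed leaky
  wall edge from Gaussian illumination is only an optional flag).
* The tracker's gait filters assume the default camera (10 fps) and gait
  (~2 Hz); other rates need `gait_ma_window` retuned to
  `frame_rate / gait_frequency`.
* The maximum of a smoothed speed trace is an extreme-value statistic:
  residual centroid noise (a few um) inflates a 200 s stage maximum by
  up to ~1%, proportionally more for slower stages — the accuracy limit of
  the confinement-ratio reproduction.
* One worm per scene is the supported regime; a second worm exists only to
  stress the selection gate.
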