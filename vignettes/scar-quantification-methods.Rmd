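---
title: "Myocardial scar quantification on joint bright-/black-blood LGE: methods and design"
author: "ScarQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocardial scar quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScarQuant)
```

## The problem

Late gadolinium enhancement (LGE) cardiac MRI is the reference standard for
imaging myocardial scar: fibrotic tissue retains contrast agent and appears
hyperintense. Joint acquisitions produce two co-registered short-axis
stacks in one scan — a bright-blood (BR) series in which the ventricular
blood pool is bright and anatomy is easy to delineate, and a black-blood
(BL) series in which blood signal is suppressed, so that scar stands out
against both the dark blood pool and the dark healthy myocardium. Because
the two series share one voxel grid, left-ventricular (LV) wall contours
drawn on the BR images transfer to the BL images by an identity mapping,
and scar detection can then be confined to the wall where the BL contrast
is most informative.

ScarQuant implements the post-processing half of that workflow: given the
two stacks, per-slice endocardial/epicardial contours, and the two
right-ventricular (RV) insertion landmarks, it detects scar within the
myocardium and reports the standard clinical quantities — scar volume,
mass, extent, per-segment infarct size on an AHA 16-segment bullseye, and
per-chord transmurality on a 100-chord bullseye. Segmentation networks and
landmark detectors are out of scope; their outputs enter as files, and a
pluggable `external` detector slot accepts any precomputed scar mask.

## Coordinate and format conventions

One convention is used everywhere: voxel arrays are `rows x cols x slices`;
pixel coordinates are 0-based and continuous with `(x, y) = (col, row)` and
the pixel center at integer coordinates; angles are degrees
counterclockwise from the +x axis in the (x, y) pixel frame. A pixel
belongs to a polygon iff its center is inside under the even-odd rule —
the simplest rule that makes rasterization reproducible to the pixel.
Stacks are NIfTI-1 (geometry from `pixdim`) or directories of 16-bit
grayscale PNG slices with a JSON geometry sidecar; contours and landmarks
are small JSON documents; all integer data round-trip losslessly.

## Scar detection

### Multi-level Otsu

On the 0–255 working scale the BL histogram of the wall is expected to be
multi-modal: suppressed blood and healthy myocardium near zero, dense scar
near the ceiling, and peri-infarct "gray zone" in between. The detector
computes three thresholds `t1 < t2 < t3` over a 256-bin histogram of the
myocardial pixels by maximizing the between-class variance of the four
resulting classes, with ties broken toward the lexicographically smallest
triple. Classification then merges the two lowest intervals: `v <= t2`
healthy, `t2 < v <= t3` gray zone, `v > t3` scar. The lowest interval
captures blood-suppressed near-zero signal, which is not a clinically
distinct tissue class. Classification compares intensities on the same
256-bin quantization used for the histogram, so a threshold and the bin it
names always agree.

The search exploits a structural fact: the lexicographically smallest
maximizer has all four classes nonempty (splitting a class with two
distinct occupied values strictly increases the objective), hence each
threshold equals the largest occupied bin of its class. Searching occupied
bins only, with precomputed class-contribution matrices, makes the exact
search fast enough to cross-check against a literal exhaustive enumeration
in the test suite. Numerical plateau ties (runs of empty bins) are
resolved with a 1e-9 tolerance so summation order cannot flip the
tie-break.

### Adaptive contrast stretch

Before thresholding, each slice is stretched so that the window between
the 1st and 99th intensity percentiles (linear interpolation between order
statistics — pinned so percentile-based tests are exact) maps to [0, 255]
with clamping. In the detection path the window is estimated from the
myocardial pixels of the slice, not the whole image: background pixels
dominate a short-axis slice, and a whole-image 99th percentile falls below
the scar mode whenever scar occupies less than about 1 % of the slice,
which would clamp gray zone and scar into one value. Estimating the window
where the analysis happens (the wall) keeps the high end of the window
inside the scar mode down to scars of about 1 % of the *wall* area. The
general-purpose `normalize255()` retains whole-slice behavior unless a
mask is passed.

### Seeded region growing

The semi-automatic alternative grows a region from a seed, slice by slice:
at each step the 4-connected neighborhood of the region (restricted to the
myocardium) is evaluated, the candidate with minimal absolute deviation
from the current region mean is admitted, and the mean is updated; growth
stops when that minimal deviation exceeds `maxDeviation` (default 25 on
the 0–255 scale, a value that comfortably separates the phantom's scar
and gray-zone modes while tolerating realistic noise) or the wall is
exhausted. Ties are broken in (slice, row, col) order so results are
deterministic. The default seed is the gravity center of the largest
4-connected scar-class component from the Otsu map, snapped to the nearest
component pixel — a wall centroid would start the growth in healthy
tissue, which cannot be what a scar-region seed means.

## Quantification

### AHA 16-segment bullseye

Slices containing myocardium are split into base/mid/apex by terciles of
slice index (remainder base-first; the basal end is configurable). Sector
boundaries derive from the two RV insertion landmarks: on basal and
mid-ventricular slices the two landmark rays bound the septal arc, its
bisector splits it into two sectors, and the complementary arc is divided
into four equal sectors — six in total; on apical slices the reversed
landmark vectors together with the septal bisector and its reverse give
four sectors. Segments are numbered counterclockwise from the anterior
insertion ray (base 1–6, mid 7–12, apex 13–16); a pixel exactly on a
boundary joins the counterclockwise-following sector. Per-segment extent
is the scar-pixel percentage of the segment; segments without myocardial
pixels are reported as missing rather than 0 so that absent coverage is
not mistaken for absent scar. The 16-segment model (no apical-cap
segment) matches the bullseye this workflow reports.

### Centerline chords and transmurality

Each contoured slice is divided into exactly 100 chords. The mid-wall
centerline is sampled at 100 angles, equally spaced about the LV centroid
(the endocardial contour centroid), starting at the anterior insertion ray
and proceeding counterclockwise — equal angular spacing is the simpler of
the two readings of "evenly spaced" and is the configurable default. The
centerline point at angle θ is the midpoint of the endo- and epicardial
ray intersections; each chord is perpendicular to the local centerline
tangent (central difference) and runs from its endocardial to its
epicardial intersection; wall thickness is the physical distance between
the two.

Transmurality per chord is scar thickness over wall thickness along the
chord: the chord is sampled every 0.25 px with nearest-pixel lookup, and
the ratio of scar samples to within-wall samples is reported. The
denominator is restricted to within-wall samples because the two end
samples of a chord round into the cavity or beyond the epicardium about
half the time; counting them would make even a fully transmural chord
read below 1. With nearest-pixel lookup the per-chord error is bounded by
roughly half a pixel over the wall depth (about 0.05 for a 10 px wall);
averages over chords are an order of magnitude tighter.

### Global metrics

Volumes are voxel counts times the voxel volume; scar mass uses the
cardiology convention of 1.05 g/cm³ for myocardial density (configurable);
extent is scar volume as a percentage of myocardial volume; mean and
maximum transmurality are taken over all chords of all quantified slices.
The clinical report (JSON + self-contained HTML with both bullseyes
embedded) copies these numbers verbatim — nothing is recomputed at render
time, so the JSON is the single source of truth.

## The phantom: what it emulates, and what it does not

`generatePhantom()` builds fully synthetic co-registered cases from an
annulus geometry: per-slice endo-/epicardial circles (the contours are the
exact circles, as 256-gon polygons), landmarks on the epicardial circle at
60° and 120° (a 60° separation mimicking septal insertion geometry), and
scar as annular sectors specified by a slice, an angular interval, and a
radial interval in wall-depth fractions — so transmurality and extent have
closed-form ground truth. BL contrast places scar at 255, healthy
myocardium in a dark band (a deterministic angular texture within 5–25,
which also guarantees the ≥ 4 distinct values multi-level Otsu needs even
without noise), and an optional gray-zone rim at 128 (2 px by default; the
rim keeps the four Otsu classes separable by construction, and no
published intensity statistics exist for gray zone on BL images — the rim
model is an assumption). BR contrast has a bright blood pool, mid-gray
wall, and dark background. Seeded Gaussian noise (clamped to [0, 255]) is
added last; identical spec and seed reproduce a case bit-for-bit.

`truthMetricsAnalytic()` derives the ground-truth metrics directly from
the construction — pixel-center membership in the circle inequalities,
independent of the polygon rasterizer — so pipeline-vs-truth comparisons
agree to within one voxel of rasterization tolerance. Default geometry
follows a typical acquisition: 1.5 × 1.5 mm in-plane, 8 mm slices.

What the phantom does **not** emulate: MR physics (no bSSFP signal model,
no inversion-recovery contrast), partial-volume gradients at tissue
interfaces, motion or breathing artifacts, intensity inhomogeneity, or
irregular scar shapes. Passing the phantom suite therefore demonstrates
the geometric and algorithmic correctness of the pipeline — not clinical
accuracy on patient data, which requires validation against expert
annotations.

## The recovery grid

`recoveryGridSpecs()` crosses transmurality (0.25–1.0), extent and noise
(0 and 10). A subendocardial sector of transmurality `T` in a wall of
inner radius `r` and thickness `w` cannot exceed an extent of
`100·T·(2r + Tw)/(2r + w)` percent even at full 360° coverage — extent
50 % at transmurality 0.25 is geometrically impossible — so the three
extent levels per transmurality are 5 %, and half and 0.9 of the
attainable maximum, capped at 50 %. Recovery is always judged against each
case's own analytic truth. At the shipped problem sizes (96 × 96 × 5,
10 px wall) the full 24-case grid recovers extent exactly and mean
transmurality within 0.011.

## Numerical choices, degenerate inputs, limitations

* Percentiles: linear interpolation between order statistics throughout.
* Multi-Otsu requires ≥ 4 distinct values; fewer is a degenerate
  histogram error. Constant stacks cannot be range-normalized.
* `maxDeviation = 0` with distinct intensities freezes region growth at
  the seed; constant intensities flood the connected wall component.
* Boundary pixels, boundary angles and candidate ties all have pinned,
  documented tie-breaks (center-in rule; counterclockwise-following
  sector; row-major order), so every result is deterministic.
* Slices whose endocardial contour vanishes (true apex) are excluded from
  chord analysis; level assignment needs at least 3 slices with
  myocardium.
* Otsu thresholding always produces a scar class — on scar-free
  myocardium it will label the upper tail of the healthy texture as scar.
  Interpreting detections on cases without visible enhancement requires
  the same caution as with any automatic thresholding method.
* Config files are YAML or JSON; flags override file values, which
  override defaults.

## Problem sizes used in the shipped checks

Tests and the acceptance script run entirely on phantoms generated at
call time: 96 × 96 × 5 stacks (wall radii 14/24 px; 16/36 px where a
20 px wall is needed for per-chord tolerance arithmetic), the 24-case
recovery grid above, 100-instance randomized histogram suites against
exhaustive search, and 7 × 7 / 8 × 8 grids for step-by-step region-growing
simulation. These sizes were chosen so every oracle is exact and the whole
suite stays comfortably interactive.
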