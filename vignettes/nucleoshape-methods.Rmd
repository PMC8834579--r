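---
title: "Quantifying nuclear shape and nuclear envelope abnormalities with nucleoshape"
author: "nucleoshape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear shape and nuclear envelope abnormalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoshape)
```

## Background

A cell type's nucleus has a characteristic shape, and departures from it —
lobulation, elongation, micronuclei, nuclear envelope (NE) blebs and
invaginations — accompany cancers, laminopathies and premature-aging
syndromes. Manual scoring of such aberrations is slow and observer-biased;
`nucleoshape` provides automated, quantitative replacements built from 2D
fluorescence micrographs: a DNA stain (DAPI/Hoechst) for nucleus
identification, optionally combined with lamin-B, lamin-A/C, LAP2 or
whole-cell channels for envelope-specific analyses.

The package has four analytical layers:

1. **Segmentation** of nuclei from the DNA channel, with QC flags for
   border-touching and mitotic nuclei.
2. **Shape descriptors** per nucleus: area, perimeter, form factor,
   eccentricity, axis ratio, solidity, mean negative boundary curvature,
   elliptic Fourier summaries, radial and point asymmetry.
3. **Detectors** for micronuclei, NE invaginations (intranuclear lamin B)
   and NE blebs (two independent pipelines).
4. A **synthetic micrograph generator** that plants all of these objects
   with known ground truth, so that every operator in the package is
   validated against planted objects rather than visual impressions.

## Segmentation model

Foreground is taken above a global threshold of the raw DNA intensities
(Otsu by default; a fixed value or a quantile can be configured — images
are never rescaled on load, so thresholds keep their physical units).
Holes in the thresholded nuclei are filled: interior shot-noise holes are
not biology, and a later erosion would inflate a single dark pixel into a
disc-sized gap. Touching nuclei are split by a watershed on the distance
transform, run independently per connected component. The watershed
tolerance (default 10 px of distance-transform depth) decides what counts
as two nuclei: small tolerances split the distance-transform maxima that
lobulated single nuclei naturally have, so the default is deep enough that
only genuinely twinned objects (two near-full-size basins) separate.

Object connectivity is 8-connected (diagonally touching pixels are one
object) with 4-connected background, the usual convention that avoids
diagonal leaks. Morphological erosions and dilations use a Euclidean disc
of the full radius rather than an iterated 3x3 cross; the iterated cross
is a Manhattan ball whose diagonal reach is only \(n/\sqrt 2\), which
under-erodes diagonal boundary stretches and lets NE-ring pixels leak
through a "shrink" step.

Two QC rules follow the common practice for nuclear morphometry:

* **Border-touching** nuclei are flagged and excluded from shape
  statistics; a truncated contour corrupts every descriptor.
* **Mitotic** nuclei are flagged when their *integrated* (summed) DNA
  intensity exceeds `median + k * MAD` across the image (default `k = 3`).
  Condensed mitotic chromatin carries the same DNA in a smaller, brighter
  footprint, so the integrated intensity — not the mean, which confounds
  with area — tracks DNA content. With fewer than 4 nuclei the robust
  statistics are meaningless and flagging is skipped with a warning.

Smoothing before thresholding (`seg_smooth_sigma`) is **off** by default:
it removes exactly the small-scale contour irregularities several of the
descriptors exist to measure. When enabled it is recorded per nucleus in
the QC table.

## Shape descriptors

All contour-based quantities start from the sub-pixel 0.5-level
iso-contour of the (hole-filled) mask, resampled to uniform arc length
(256 points by default). On binary masks this polygon still carries
stair-step bias — it measures a radius-50 disk at form factor 0.89 — so
the resampled contour is smoothed with a periodic Gaussian of 1.5 px of
arc length before perimeter and curvature measurement. After smoothing the
same disk measures 0.997, and supersampled coverage images measure 0.992
without any help; the analytic anchor "circle = 1" is what this estimator
is built around.

* **Form factor** \(4\pi A/P^2\): 1 for a circle, below 1 for lobulated or
  blebbed outlines. Area is the pixel count; perimeter the smoothed
  contour length. Values above 1 can only come from estimator bias and are
  clipped with a warning.
* **Eccentricity and axis ratio** come from the moment-equivalent ellipse
  (principal second central moments \(\lambda_1 \ge \lambda_2\)):
  \(e=\sqrt{1-\lambda_2/\lambda_1}\), axis ratio
  \(\sqrt{\lambda_1/\lambda_2}\). This is the convention of mainstream
  region-analysis software; the literal bounding ellipse is not used.
  Degenerate (collinear) objects report \(e=1\) with a flag.
* **Solidity** divides the object area by the number of pixel centres
  inside or on the convex hull of the object's pixel centres — both areas
  on the same pixel-counting convention, with exact integer arithmetic, so
  the value matches an exhaustive brute-force computation identically.
* **Mean negative curvature** is the mean of the signed curvature over the
  concave arcs of the boundary (0 for convex shapes). Curvature comes from
  central differences of the arc-length-resampled, periodically smoothed
  contour; the smoothing scale (default 2% of the contour length) is a
  real parameter of the measure — raster contours need it, analytically
  sampled contours can use much less. The sign convention follows the
  contour orientation, which the package normalises so that concave means
  indenting toward the nuclear interior.
* **Elliptic Fourier descriptors** (EFD) expand the closed contour in
  harmonic ellipses with the classic closed-form coefficients for a
  piecewise-linear contour, parametrised by arc length. Two summaries are
  offered: `harmonics_needed`, the smallest number of harmonics whose
  reconstruction stays within `(1 - fidelity) x equivalent radius` of the
  contour (default fidelity 0.95), with deviation measured *geometrically*
  (distance to the nearest reconstructed point) so that a pure
  reparametrisation costs nothing; and `coefficient_ratio`, the energy
  ratio \(\sum_{n\ge 2} E_n / E_1\) with
  \(E_n=a_n^2+b_n^2+c_n^2+d_n^2\) over a fixed 20 harmonics — rotation-
  and phase-invariant and with a large dynamic range for shape
  deformation. Note that under the arc-length parametrisation an ellipse
  retains a little energy above the first harmonic (about 0.6% for a 2:1
  ellipse); a circle is the true null of this statistic.
* **Radial asymmetry** counts object pixels outside the largest inscribed
  circle (centre at the distance-transform maximum, ties broken by the
  lexicographically smallest (row, col); radius equal to that maximum).
  **Point asymmetry** counts pixels whose reflection through the centroid
  (rounded to the nearest pixel) is not an object pixel. Both are emitted
  as raw counts and as fractions of the area.

Descriptor sensitivities differ by design: elongation moves eccentricity
but barely touches solidity; lobulation crushes solidity and form factor;
a bi-lobed outline is picked up most strongly by mean negative curvature.
The test suite asserts this ordering on a canonical panel of synthetic
shapes, plus scale and rotation invariance (within 2% at the package's
rendering resolution) for the dimensionless descriptors. Mean curvature
has units of 1/px and scales accordingly.

## Micronucleus detection

The detector follows the high-content screening recipe: identify objects
from the nuclear stain with a dual-threshold pass (the primary threshold
for nuclei, a second pass at `mn_low_thresh_scale` times the primary for
dim candidates), clean the nucleus masks by an opening of radius
`cleanup_iter` ("sequential erosion and dilation"), approximate each
cell's territory by dilating its nucleus by `cell_dilation_px` (default
25 px; a whole-cell stain can replace this), resolve territory collisions
by nearest-nucleus propagation, and classify each candidate by
*comparative size within its cell*: a candidate whose centroid falls in
the territory of nucleus \(k\) is a micronucleus when its
equivalent-circle diameter \(\sqrt{4A/\pi}\) is at most 1/3 of the
nucleus' equivalent diameter. Candidates failing the ratio are reported as
unclassified; candidates outside every territory are discarded. The
micronuclear frequency is the percentage of nuclei with at least one
associated micronucleus — a nucleus with three counts once.

The 1/3 ratio is applied inclusively: a candidate exactly at the threshold
is accepted, one pixel of extra area rejects it. Both edges are pinned by
tests on constructed masks (areas 900 vs 100 and 101).

## Invagination detection

NE invaginations (the nucleoplasmic reticulum) are lamin-coated tubes in
the nuclear interior, detected here by the presence of lamin B away from
the rim: nuclei come from the DNA channel; high-lamin-B objects are
thresholded per nucleus; the nucleus mask is shrunk by `shrink_px`
(default 4 px, which must exceed segmentation jitter plus the lamin ring
width); lamin pixels inside the shrunken mask are intranuclear, the rest
is NE rim and is excluded. Components of the clipped intranuclear mask of
at least `inv_min_size` px² are counted as invaginations; a 1-px opening
(`inv_open_px`) removes the hairline leaks the rim can push past the
erosion. Exclusion is pixel-level by construction: an invagination tube
physically joins the NE, so its thresholded component usually *contains*
rim pixels, and any component-level majority rule would delete true
invaginations along with the rim.

The per-nucleus threshold is Otsu on the in-nucleus lamin intensities by
default rather than a fixed quantile: the bright fraction of a nucleus
varies with its invagination load (roughly 15% for a bare rim to 40% with
five tubes), and any fixed quantile is wrong at one end of that range — it
either lands inside the noise or cuts into the lamin class and speckles
the tubes. A quantile mode remains available (`inv_threshold_quantile`).
A bimodality guard (`min_contrast`, default 3) handles the structureless
case: Otsu applied to pure noise always "finds" a split, but the split
separates the class means by only ~2.7 truncated-class standard
deviations, while genuine lamin structure at the package's study
conditions scores 3.4 or higher; nuclei under the guard report no lamin
objects at all.

## Bleb detection

Blebs are protrusions through a local gap in the lamina, typically lamin-B
negative and with dimmer DNA than the nucleus body. Two pipelines:

* **Lamin-gap subtraction** (needs DNA + lamin B): per cell territory the
  chromatin object is segmented with a deliberately permissive threshold
  (per-cell Otsu scaled by `bleb_dna_scale` = 0.5 — blebs often contain
  less DNA, so the ordinary threshold would amputate them), the lamin-B
  object is thresholded, lightly closed and hole-filled, and the bleb is
  the chromatin that remains after subtracting the (2-px dilated) lamin-B
  object, within an area band and adjacent to it. The dilation suppresses
  the 1-2 px sliver of chromatin that rings the lamin object simply
  because the permissive DNA threshold reaches further out than the lamin
  threshold; adjacency is tested against the dilated object for the same
  reason. Isolated bright lamin specks (under 9 px) are removed before
  object building — inside a bleb, a couple of noise pixels would
  otherwise punch dilated holes through the candidate. By construction
  detected bleb pixels never intersect detected lamin-B pixels, and only
  chromatin-containing blebs are detectable by this route.
* **Morphological cut-off** (single NE/nucleoplasm stain, e.g. LAP2): the
  nucleus cleanup opening is run at its maximum strength
  (`bleb_max_iter`, default radius 8) so blebs are cut off the main
  shape; residual components must touch the nuclear core (8-adjacency),
  and residuals that are small *and* round (area < 150 px² and form
  factor > 0.85) are rejected as micronuclei — the conjunction, so small
  irregular blebs survive. Geometry dictates the opening radius: a disc
  of radius \(r\) fits inside a hemispherical bump of radius \(\ge r\),
  so the opening only removes blebs strictly smaller than its radius.

Per-bleb outputs include the relative area (bleb area over nucleus area),
and, per optional channel, the enrichment (mean intensity over the bleb
divided by mean intensity over the lamin-B object) — the readout used for
recruitment of proteins such as lamin A/C to bleb sites. Bleb frequency is
the percentage of nuclei with at least one bleb.

## The synthetic generator and what passing tests mean

`scene_spec()`/`render_scene()` draw nuclei as Fourier-perturbed ellipses
(base radius 34-46 px, axis ratio 1-1.4, low-order radial perturbations)
on a jittered grid, then render per nucleus: the DNA channel fills the
body at `dna_level` (default 100) and any bleb at `bleb_dna_frac` (0.6);
the lamin-B channel is a rim of width 3 px at `lamin_level` (120)
interrupted at the bleb neck, plus intranuclear tubes (width 3.5 px,
parallel non-crossing chords) for planted invaginations, over a diffuse
nucleoplasmic pool at 45% of the rim level — real lamin B1 staining has
such a pool, and it is what makes "the filled lamin-B object" well defined
even at a wide bleb gap; the lamin-A/C channel fills the body and is
enriched in blebs so that the *raw* mean ratio equals the planted
enrichment (1.5 by default). Micronuclei are disks at 0.15-0.25 of the
nucleus' equivalent diameter placed in the territory near their nucleus;
blebs are disks of radius 6-7 px centred 0.3 radii outside the boundary
(a balloon on a neck, not a half-embedded hemisphere). Everything is
rendered with 4x supersampling and box down-sampling so that sub-pixel
coverage, not rasterization bias, sets the edge profile; Gaussian noise
(sd 20, i.e. SNR 5 against the DNA level) and optional Poisson shot noise
come last. A fixed seed gives bit-identical scenes.

Planted tube combs are jittered as a whole rather than per tube: with
per-tube jitter the worst-case inter-tube gap fell below 3 px, which a
single bright noise pixel bridges under 8-connectivity — and two bridged
tubes *are* one object to any object-counting pipeline, so separability
is part of the planted condition, not something the detector is asked to
invent.

What the synthetic scenes do **not** emulate: optics (no PSF, no
out-of-focus light), chromatin texture, clustered or overlapping cells,
illumination gradients, histology stains, 3D structure, or time. Passing
the planted-recovery suites therefore demonstrates that the *algorithms*
implement their definitions correctly at realistic geometry and SNR — it
does not certify performance on any particular microscope's images, where
thresholding and the territory approximation are the components most
sensitive to reality.

## Validation summary (computed by the test suite)

* Analytic anchors: circle form factor 1 (exact on closed-form inputs,
  within 0.02 when rasterized), circle eccentricity 0, 2:1 ellipse
  eccentricity within 0.02 of \(\sqrt 3/2\) at any rotation.
* Solidity and point asymmetry match exhaustive brute-force pixel
  computations *exactly* on 100 random blobs.
* Mean negative curvature agrees within 5% with the closed-form polar
  curvature on a bi-lobed test curve; EFD energy ratios agree within 10%
  with a trapezoid-integration Fourier oracle.
* Planted recovery at SNR 5: micronuclei (500 nuclei, 20% frequency)
  sensitivity >= 0.95, FDR <= 0.05 at IoU >= 0.3, frequency inside the
  95% binomial interval of the realised truth; invagination counts 0-5
  exact in >= 90% of 200 nuclei; bleb methods >= 90% concordant over 300
  nuclei with the planted 30% prevalence recovered within its binomial
  interval.
* Determinism: identical seeds and configurations give byte-identical
  images and CSVs.

The problem sizes above (10, 4 and 6 scenes of 50 nuclei for the three
detector suites; scene sizes 1500x1320 and 1200x1050 px) are the package's
validation conditions; they keep each suite in the minutes range on one
CPU while providing the nucleus counts the statistics need.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on a 256-bin histogram of the raw values;
  on a plateau of equally optimal bins (noiseless two-level images) the
  middle bin is taken, not the first.
* Ties in the distance-transform maximum (inscribed-circle centre) break
  to the lexicographically smallest (row, col).
* Blank images segment to an empty mask with a warning, not an error.
* A nucleus erased by the invagination shrink reports zero interior with
  a `vanished` flag.
* Empty regions make enrichment `NA` with a warning.
* Labels are always consecutive 1..count in raster order, so reruns are
  label-stable.

## Known limitations

* 2D only; NE folds seen face-on are indistinguishable from invaginations
  in 2D, and 3D descriptors are out of scope.
* The lamin-gap bleb method cannot see chromatin-free blebs (documented
  behaviour, asserted in tests); the morphological method cannot see
  blebs rounder and smaller than its rejection filter.
* Rupture state of blebs/micronuclei is not assessed; combine with
  live-cell rupture reporters where that matters.
* The micronucleus/nucleus split is purely size-based; fragments of dead
  cells of micronucleus-like size inside a territory would be counted.
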