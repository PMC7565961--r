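---
title: "Automatic cardiomyocyte morphometry and connexin-43 lateralization"
author: "myomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic cardiomyocyte morphometry and connexin-43 lateralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomorph)
```

## The problem

Cardiomyocyte (CM) geometry and the amount and localization of connexin 43
(CX43) shape electrical conduction in the heart. CX43 normally concentrates
in gap junctions at the intercalated discs — the longitudinal ends of the
cells — and its displacement to the lateral cell membrane (lateralization)
accompanies many arrhythmogenic conditions. Quantifying cell dimensions and
the polar-versus-lateral split of CX43 from immunofluorescence images by
hand is slow enough that studies typically analyze only small tissue
regions. `myomorph` automates the whole chain: cell mask construction from
multi-channel fluorescence images, per-cell delineation and morphometry,
CX43 expression and lateralization quantification, and agreement scoring
against manually drawn masks.

## Input model

A field of view is a `channel_set` of calibrated 8-bit channels sharing one
scale (micrometers per pixel):

* `c1` — a cytoplasmic CM marker (SERCA2 in human sections, F-actin in rat
  sections); the basis of the cell mask.
* `c2` — CX43 (optional).
* `c3` — interstitium, e.g. WGA-stained extracellular matrix (optional).
* `c4` — a raw duplicate of `c2`, kept separately because CX43
  quantification always applies its own histogram equalization and a fixed
  high threshold, independently of how `c2` is processed for cell-mask
  building.

Merged RGB images (common for two-marker rat acquisitions) are split into
roles by plane selectors; a white CX43 signal is recovered as the pixelwise
minimum of the R, G and B planes, since white is the only signal high in
all three. RGB inputs to grayscale roles are averaged with half-up
rounding. Sources deeper than 8 bits are linearly rescaled on load, because
every threshold in the configuration is defined on the 8-bit range.

All raster geometry uses one convention, stated once: row-major matrices,
origin at the top-left, pixel `(row, col)` occupying the unit square with
center `(col - 0.5, row - 0.5)`, and angles measured from the +x axis with
y pointing down, normalized to (−90°, 90°].

## From channels to masks

Each channel is optionally histogram-equalized, binarized (`pixel > thr`,
strictly), opened with an `nr × nr` square window (erosion then dilation:
deletes isolated specks smaller than the window while preserving large
objects), and grown by `ng_it` dilations with an `ng × ng` window to
compensate the tissue lost to noise removal. Rank 1 means "no
transformation", so a configuration with `nr = ng = ng_it = 1` reduces the
whole stage to pure thresholding — a property the test suite asserts
directly. Structuring elements are squares of ones; for the occasional even
rank the anchor is the top-left pixel of the central 2×2 block, and
out-of-image pixels count as background. These conventions make every
morphological result bit-reproducible.

The automatic CM mask activates a `Mc1` pixel unless it is active in *both*
`Mc2` and `Mc3` (union of `Mc1 & !Mc2` and `Mc1 & !Mc3`). Absent channels
enter as all-zero masks, so single-channel inputs degenerate to
`Ma = Mc1`; for two-channel inputs without an interstitium stain an
optional switch (`invert_c3`) substitutes the complement of `Mc1`. The
tissue mask `Mt` is the union of the three channel masks, and the CX43
quantification mask `Mc4` is the equalized `c4` binarized at `thr_c4`
(default 254, keeping roughly the top percentile of the equalized
distribution) with no morphology at all.

Histogram equalization follows the cumulative-distribution form
`round((cdf(v) − cdf_min) / (N − cdf_min) · 255)` with `cdf_min` the CDF of
the lowest occupied level: monotone, lowest occupied level to 0, highest to
255. A channel whose histogram has a single occupied level is returned
unchanged — the only convention under which `Mc4` of a constant channel is
well-defined (all-ones only if the constant exceeds the threshold). This
degenerate case is documented here precisely because no remapping of a
one-level histogram is canonical.

## Cell delineation and morphometry

Foreground components of the mask are labeled with 8-connectivity (diagonal
contacts join, so obliquely adjacent boundary pixels do not fragment a
cell) and each component's outer boundary is traced by clockwise Moore
border following; internal (hole) contours are never emitted. Components
are reported top-to-bottom, left-to-right by their first raster pixel,
which fixes stable record ids. The enclosed area uses the lattice-point
correction `shoelace + B/2 + 1` over the traced polygon (`B` = distinct
boundary pixels), which equals the exact enclosed pixel count for
simply-connected shapes — a 10×10 square yields exactly 100 px², matching
the counting oracle in the tests.

Contours must exceed 100 µm² in area and 40 µm in perimeter (strict) to
survive; filtering before rectangle fitting keeps the expensive stages off
implausible blobs. Each surviving contour is enclosed in its minimum-area
rotated rectangle via rotating calipers over the convex-hull edges (the
optimal rectangle is flush with a hull edge, so the search is exact; ties,
e.g. squares, resolve to the first minimizing edge). The rectangle is then
expanded by projecting each vertex away from its diagonal partner by `h`
pixels — a similarity transform with ratio `(d + 2h)/d` on the diagonal
`d`. Morphometry is:

* length `L` = scale × mean of the fitted and expanded long sides,
* width `W` = scale × the fitted short side,
* `R = L/W`, `A = L·W`,

and cells must satisfy `20 < L < 200` µm, `5 < W < 50` µm (strict). The
averaging of fitted and expanded long sides commutes with the micrometer
conversion, so the order is irrelevant; we convert last.

The padding default derives from the CX43 channel's growth parameters as
`h = 2 · ng_c2 · ng_it_c2` — dilating `Mc2` eats into the cell mask, and
the box must grow back over the eaten margin to keep the polar
compartments on the intercalated discs. When `ng_c2 = 1` no dilation is
applied anywhere, so there is nothing to compensate and the derived
padding is 0 rather than the literal `2·1·ng_it` (an explicit `h` in the
configuration always wins). With the default three-channel configuration
(`ng_c2 = 3`, `ng_it_c2 = 5`) the padding is 30 px.

## CX43 expression and lateralization

Global expression is `Cex = 100 · |Mc4 ∩ Mt| / |Mt|`, and the off-tissue
noise level is `r = 100 · |Mc4 \ Mt| / |¬Mt|`; at the default `thr_c4 =
254` the design point is `r < 0.1%` with `Cex` at most a few percent.
Tissue area is reported both as the active-pixel count and as the largest
external contour of `Mt`, in mm².

Each expanded cell rectangle is rasterized under a single pixel-center
rule — a pixel belongs to the box iff its center lies inside or on the
boundary (10⁻⁷ px tolerance) — and cut by three lines perpendicular to the
long axis into four equal-length compartments: `H0`, `H3` at the poles,
`H1`, `H2` in the middle. A center exactly on a cut goes to the
lower-index compartment, so compartments are disjoint and cover the box
exactly (asserted as a set-algebra property in the tests). The denominator
of each compartment fraction `Fi = |Hi ∩ Mc4| / Ni` counts *all* box
pixels inside the image, not only tissue pixels — the literal reading of
the compartment definition; restricting to tissue pixels would silently
change `Fi` on cells touching dark regions. Lateralization is

$$C_{lat} = 100 \cdot \frac{F_1 + F_2}{F_0 + F_1 + F_2 + F_3},$$

0 when all CX43 is polar, 100 when all is lateral. Cells with no CX43
signal in their box are *flagged* (`no_signal`) and excluded from
distributions rather than coded as 0, which would inflate the lowest
histogram bin.

The population distribution of `Clat` is summarized by fitting
`f(x) = a·e^{−bx}` to the density histogram (default bin width 5 percent,
nonlinear least squares started from a log-linear regression). The
closed-form integral `(a/b)(e^{−b·lo} − e^{−b·hi})` then gives the
fraction of cells in any lateralization range. For the reference model
`a = 0.03425`, `b = 0.033` the integral over [0, 20] gives 0.50 and over
[0, 50] gives 0.84 — both recomputed, not asserted as constants, by
`scripts/acceptance.R` and the test suite. The binning behind any
particular published pair of constants is not recoverable from the
constants alone, so the fit is validated by noiseless inversion (a
histogram generated from the model recovers `a` and `b` to 10⁻⁶) and by
parameter recovery from 50 000 truncated-exponential draws (rate recovered
within 10%).

## Manual-versus-automatic agreement

Manually delineated masks enter through the *same* contour-and-rectangle
stage as automatic masks, because the overlap measure is defined on
enclosing rectangles. For manual cell `i` and automatic cell `j`,
`I_{i,j} = 100 · |raster(B_i^m) ∩ raster(B_j^a)| / |raster(B_i^m)|` —
deliberately normalized by the manual area only, hence asymmetric (a small
manual box inside a large automatic box scores 100, not vice versa; the
suite asserts this asymmetry). `I_i` is the row maximum (0 with no
automatic cells), and cells with `I_i > 50` (strict) count as matched. The
percentile curve `Pc(k)`, `k = 1..100`, uses linear interpolation between
closest order statistics (quantile type 7) — the integer-percentile curve
is smooth rather than a step function; the AUC is its trapezoidal integral
scaled to [0, 1], closed at the right edge with `Pc(101) := Pc(100)` since
integer percentiles stop at 100. Under this formula a constant curve at c
integrates to exactly c/100, and self-evaluation yields AUC = 1.

## Synthetic scenes and what they validate

The generator renders fields of rectangular cells at arbitrary
orientations with exact vector ground truth: `c1` bodies at intensity 200,
`c2` CX43 at 255 (so the equalized 254 threshold captures it), `c3` a thin
halo around each cell. Per cell, a CX43 pixel budget of
`0.5 · min(|polar set|, |lateral set|)` is split between 4-px polar bands
and 2-px lateral strips according to the planted lateral fraction φ;
lateral strips live strictly inside the middle half of the cell so the
planted fraction is recovered as `Clat ≈ 100φ` when the detected box is
right. Defaults — 768×768 px at 0.21 µm/px, five non-overlapping cells
(≥ 3 px gaps) of 30–60 µm × 10–20 µm, φ ~ U(0, 0.6) — describe a clean
longitudinal ventricular section at confocal resolution; the length range
sits inside the plausibility window because fields of view at this scale
cannot hold several 200 µm cells. All sampling derives from one scene
seed; rendering is bit-reproducible.

Clean scenes are analyzed with an identity-morphology configuration (pure
thresholding, `h = 0`): with no noise there is nothing to open, and no
CX43 dilation means no padding compensation. Over 20 seeded scenes of 5
cells the pipeline recovers every planted cell, mean |L − L_true| within
2 × scale µm, mean |Clat − 100φ| within 5 points, and AUC ≥ 0.9 against
the ground-truth mask (the acceptance suite runs exactly this).

What synthetic scenes do **not** show: real CMs are not perfect
rectangles; real CX43 bands are discontinuous and partially out of plane;
brightness heterogeneity, blur and antibody background are far richer than
salt noise and a linear ramp; and touching cells without interstitial
staining — the main failure mode on real two-channel images — are excluded
by construction (the generator keeps cells disjoint; merging behavior can
be stressed separately by disabling the halo and morphology). Passing the
recovery suite therefore certifies the geometry and counting machinery,
not biological segmentation accuracy on real tissue.

## Numerical choices and degenerate inputs

* Strictness: all plausibility filters and the 50% match are strict
  inequalities; thresholding is `> thr`.
* Boundary tolerances: rasterization 10⁻⁷ px; min-area rectangle ties
  10⁻¹² relative; vertex-projection identity validated to 10⁻⁹ px.
* Degenerate contours (collinear, < 3 distinct points) raise
  degenerate-geometry errors and are skipped by the detector; single-pixel
  contours have area 1, perimeter 0 by convention (they never pass the
  filters).
* Empty tissue masks make `Cex` undefined (error), full-image tissue masks
  make `r` undefined (error); the pipeline runner degrades these to `NA`
  in summaries.
* The exponential fit refuses fewer than two occupied bins.
* No stage of the detection pipeline uses randomness; only the synthetic
  generator does, through its explicit seed.

## Problem sizes

The shipped tests run on 300–768 px synthetic fields with 2–5 cells per
scene and a 20-scene recovery experiment; these sizes were chosen so the
whole validation cycle completes in minutes on a laptop while every
geometric property is exercised at realistic cell-to-image ratios.
Processing cost scales linearly in pixels for mask building and in
boundary length for tracing; fields of several thousand pixels per side
remain practical.
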