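---
title: "Methods: quantifying multi-zone paper-supported 3D cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying multi-zone paper-supported 3D cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Stackable paper sheets patterned with printed wax barriers carry rectangular
arrays of circular hydrophilic zones (the standard layout: 96 zones, 9 mm
pitch, 5 mm diameter). Each zone holds a ~200 µm slab of cell-laden hydrogel;
stacking sheets assembles arrays of 3D cultures, and peeling a stack apart
"sections" every culture at once. A flatbed fluorescence gel scanner then
images each layer at 100 µm resolution, so one grayscale raster per layer and
channel encodes where the labelled cells are.

Wet paper is soft: on the scanner bed it compresses, bends and buckles, so
the zone array in the image cannot be mapped by a rigid grid nor corrected by
a global Euclidean transform. zonestack's answer — like the original
interactive workflow it reimplements programmatically — is to re-find each
zone *locally*: partition the region of interest into an `n_rows x n_cols`
grid of cells and fit the zone border independently inside each cell.

## Zone detection

Within each grid cell we compute Sobel gradient magnitudes (after Gaussian
pre-smoothing, `blur_sigma = 1` px) and threshold them with Otsu's method to
get binary edges; the wax barrier is detectable because wax-impregnated and
bare paper differ in autofluorescence. Two details matter:

* **Threshold domain.** Otsu is applied to `log1p(gradient magnitude)`, not
  the raw magnitude. A cell often contains two edge populations — the strong
  border of the bright cell-laden disc and the much weaker wax/paper
  border — plus a noise floor. On the raw scale Otsu separates strong from
  weak edges and discards the wax border; on the log scale it separates all
  edges from the noise floor, which is what the circle fit needs.
* **Fixed-radius fit.** The zone radius `R` is known from the plate design,
  so the fit searches only over centre positions, scoring each candidate by
  the fraction of the radius-`R` circumference supported by edge pixels
  (equivalently, a single-radius circular Hough accumulation, computed as
  one convolution with a one-pixel-wide ring kernel). Ties are broken toward
  the grid-cell centre, and the final centre is the support-weighted
  centroid of the near-maximal accumulator plateau (within 98% of the
  maximum, in a ±4 px neighbourhood), which resolves the half-pixel
  ambiguity of a lattice argmax.

A fit whose edge support (`fit_quality`) is below 0.3 is returned as
`provenance = "failed"` — flagged for manual correction via
`override_zone()`, never silently guessed. On clean synthetic sheets the fit
quality of a full-contrast circle exceeds 0.95.

## Quantification and calibration

For a fitted zone, `zone_intensity()` averages pixels whose centres lie
within `R` and subtracts the mean over a one-pixel-wide circumference at
`1.2 R`, which crosses wax-patterned paper holding no cells — a thin ring,
not an annulus, and local to each zone. Negative corrected intensities are
kept in tables (they are evidence of background over-subtraction) and floored
to zero only when converted to cell counts.

Calibration fits corrected intensity against known seeded cells. The default
form is a saturating hyperbola with an additive offset,

$$ I(c) \;=\; b + I_{\max}\,\frac{c}{c + K}, $$

chosen because integrated fluorescence saturates at high label density. The
offset `b` is there for a specific reason: the background circumference lies
on wax while the zone interior is bare paper, so the corrected intensity of
an empty zone is not zero but (paper − wax) autofluorescence; `b` absorbs
exactly that. A linear form is available for proportional regimes. The
inverse mapping converts intensity to cells, flags intensities above the
fitted range as extrapolations, and maps non-positive corrected intensities
to zero cells.

Two properties of this design are worth knowing. A cell-free rim (below)
scales the effective amplitude $I_{\max}$ of a plate-fitted curve but leaves
$K$ untouched, so half-saturation is recoverable from imaged plates even
when the rim fraction is unknown. And because non-positive corrected
intensities clip to zero cells, zones whose true signal is smaller than the
wax/paper background offset lose their estimate — self-calibrated counts are
accurate in the median but not for the dimmest zones.

## Half-radial profiles and heat maps

Cylindrical 3D cultures should be rotationally symmetric, so a 1D radial
profile represents them compactly — and computing the two halves separately
makes the symmetry assumption *checkable*. `half_radial_profile()` bins
pixels into concentric one-pixel rings (`ring r`: `r − 1 < d ≤ r`, with the
exact-centre pixel assigned to ring 1 so the rings partition the covered
disc) and splits each ring by the axis through the centre (`axis_angle = 0`
is vertical; pixels exactly on the axis go left — deterministic, at the cost
of an exact left/right swap identity only when no pixel sits on the axis).
`n_rings = ceiling(outer_factor × R)` with `outer_factor = 1.1`, so the
outer ~10% of every profile samples background: 33 rings for a 3.0 mm zone
at 100 µm pixels.

Heat maps arrange profiles as `[rev(left), right]` rows (the zone centre
mid-row), replicates stacked vertically, experiments concatenated as column
blocks, and layers stacked L1-on-top; rendering inserts black separators
between experiments and white separators between layer bands. The printed
artifacts this reproduces are internally inconsistent about ring counts
(33 rings per half, yet 8×76 and 8×456 heat maps imply 38), so `n_rings` is
configuration: the default follows `ceiling(1.1 R)`, and 38 reproduces the
8×76/8×456 shapes when asked.

## Stack statistics

`stack_total()`, `enumerate_stacks()` and `growth_table()` are bookkeeping:
seeded totals (e.g. eight H layers at 120,000 cells/zone = 960,000 cells in
a 1600 µm stack), one stack per (geometry, replicate) pair with missing
zones treated as assembly errors, and per-layer estimated/seeded ratios
across replicates (SD reported as absent, not zero, for a single replicate).

`compare_conditions()` is a two-sided Welch t-test (the unequal-variance
default is the robust choice where only "t-test" is specified;
pooled-variance is available). Degenerate zero-variance groups follow the
natural limits — equal constants give statistic 0 and p = 1, unequal
constants a signed infinite statistic and p = 0 — because `stats::t.test`
refuses essentially-constant data outright.

Migration from a sender layer to an adjacent receiver is
`receiver / (receiver + sender)`, computed on background-corrected
fluorescence of the label rather than converted counts: the definition is a
signal ratio, it is scale-invariant, and conversion through a nonlinear
calibration would break that invariance. `directionality()` pairs up/down
fractions per sender across replicates (ratio of means plus a paired
t-test); outermost senders with a single neighbour are reported unpaired.
No multiple-testing correction is applied anywhere; with six layers and
several conditions this is a real limitation users should weigh.

## The synthetic sheet generator

Every stage is validated against `generate_sheet()`, a forward model with
known ground truth:

* **Geometry.** Zones of radius `R` on the analytic grid; each zone is a
  cell-laden disc of radius `(1 − rim_fraction) R` (default 0.15 — the
  midpoint of the 10–20% cell-free rim that capillary wicking produces in
  spotted gels), a bare-paper annulus out to `R`, and wax background
  outside.
* **Optics.** Disc intensity is `paper_bg` plus the forward fluorescence
  model of its cell count (default hyperbola, `I_max = 40000`, `K = 1e5` on
  a 16-bit scale, in the range where a 4 µL spot of 0.1–5 × 10⁷ cells/mL —
  4,000 to 200,000 cells — spans the curve's knee). `paper_bg = 2000`,
  `wax_bg = 5000`: enough contrast for edge detection, both small against
  the signal. No scanner point-spread function is modelled: at 100 µm
  resolution the blur is sub-pixel.
* **Distortion.** A smooth random displacement field (sum of six Gaussian
  radial-basis bumps of scale `warp_scale_px`, rescaled to a maximum
  displacement of `warp_amplitude_px`) emulates compression, bending and
  buckling without a mechanical paper model. Ground-truth centres are the
  fixed points of the warp applied to the analytic grid; configurations
  whose warped zones would overlap are rejected. An optional global
  anisotropic scaling emulates wet-paper expansion (off by default).
* **Noise.** Additive i.i.d. Gaussian, applied last. All randomness is
  seeded; identical parameters and seed give bit-identical images.

What the generator does *not* emulate — growth, death, migration, oxygen
gradients, ring-shaped survival patterns as emergent phenomena (it can paint
such patterns, not cause them), scanner vignetting, or spatially correlated
paper texture — bounds what passing tests mean: they validate the
*measurement* chain, not any biological model. Performance figures obtained
on synthetic sheets (e.g. the ≥98% automatic detection rate at 3 px warp and
5% noise) are statements about this forward model, chosen to be conservative
relative to flat-bed scans of clamped wet paper, not guarantees on any
particular scanner.

## Numerical choices and test scale

Pixel coordinates are 0-based `(x, y)` with origin top-left; physical
lengths are micrometres, converted at the raster boundary. Pixel membership
is by pixel-centre distance; the background circumference is the pixel set
whose distance rounds to `round(1.2 R)`. Brute-force per-pixel loops (an
independent oracle implemented in the test suite) must agree with the
vectorised implementations to summation-order epsilon, with identical pixel
counts per bin.

The test suite simulates at the study geometry: 96-zone sheets for the
detection-rate check (20 sheets, seeds fixed, ~1 s each), an
8-concentration × 12-replicate plate for calibration recovery (parameters
within 5%, median per-zone count error within 5% at 2% noise), 10,000 null
draws for the Welch test size (0.05 ± 0.01 at n = 8 per group, the standard
replicate count), and a 48-zone, 8-layer set plus a calibration sheet for
the end-to-end pipeline. These sizes keep the full suite under a minute of
simulation-heavy work while exercising every printed-arithmetic identity
(33 rings; 120,000 and 12,000 seeded cells; 960,000 cells / 1600 µm per
all-H stack; 48 stacks from six geometries × eight replicates; 8×76 and
8×456 heat maps).
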