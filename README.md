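# zonestack

Quantitative image analysis of multi-zone, paper-supported 3D cell cultures.

## The problem

Wax-patterned paper sheets carry arrays of circular culture zones (the
standard layout: 96 zones, 9 mm pitch, 5 mm diameter), each holding a
~200 µm slab of cell-laden hydrogel. Stacking sheets assembles arrays of 3D
cultures; peeling a stack apart sections every culture at once, and a
fluorescence gel scan of each layer (typically 100 µm/pixel, 16-bit TIFF)
encodes the 3D distribution of labelled cells as a set of flat images.

Quantifying those images is harder than quantifying rigid arrays: wet paper
compresses, bends and buckles on the scanner bed, so the zone grid is
distorted in ways no global rotation or affine transform fixes. zonestack is
a library + CLI for this workflow, aimed at labs running paper-based 3D
culture (CiGiP-style) experiments:

* **Zone detection** — per-grid-cell Sobel/Otsu edge extraction and a
  fixed-radius circle fit (single-radius circular Hough): for each zone the
  centre maximising edge support on the circumference of known radius *R*.
  Zones without an acceptable fit are flagged `failed` for manual override,
  never guessed.
* **Quantification** — mean intensity inside the fitted circle minus the
  local background sampled on a one-pixel circumference at 1.2 *R* (on
  cell-free wax-patterned paper).
* **Calibration** — corrected intensity vs seeded cells, default form
  *I*(*c*) = *b* + *I*<sub>max</sub> · *c* / (*c* + *K*), inverted to convert
  intensities to cell counts.
* **Half-radial profiles & heat maps** — per-ring mean intensities computed
  separately for the two halves of each zone (φ ∈ (0, π) and (π, 2π)),
  assembled as replicates × (experiments · 2 *n*<sub>rings</sub>) heat maps,
  layers stacked L1-on-top.
* **Stack statistics** — seeded totals, per-layer growth ratios, Welch
  t-tests between conditions, and migration fractions
  receiver / (receiver + sender) with up/down directionality.
* **Synthetic sheet generator** — a seeded forward model (zone discs with
  cell-free rims, wax/paper contrast, smooth non-rigid warps, additive
  noise) with exact ground truth, so every stage is testable without a
  scanner.

## Worked example

Simulate a warped, noisy 96-zone sheet holding eight seeding densities
(4,000–200,000 cells/zone, one per row), detect the zones, calibrate, and
convert intensities back to cell counts:

```r
library(zonestack)

params <- sheet_sim_params(n_rows = 8, n_cols = 12, warp_amplitude_px = 3,
                           warp_scale_px = 200, noise_sd = 500, seed = 42)
levels <- round(4000 * 50^((0:7) / 7))     # 8 seeding densities
sim <- generate_sheet(params, matrix(levels, 8, 12))

grid <- grid_spec(8, 12)                   # 9 mm pitch, 5 mm zones
fits <- detect_zones(sim$image, grid)
table(fits$provenance)
#> auto
#>   96
summary(fits$quality)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9583  1.0000  1.0000  0.9968  1.0000  1.0000

zones <- measure_zones(sim$image, fits)
m <- merge(zones, sim$truth, by = c("row", "col"))
curve <- fit_calibration(cells = m$cells, corrected = m$corrected)
print(curve)
#> <calibration_curve> form=hyperbola; b=-2995, I_max=2.915e+04, K=1.007e+05; fitted on 96 points, cells in [4000, 200000]

est <- cells_from_intensity(curve, m$corrected)
median(abs(as.numeric(est) - m$cells) / m$cells)
#> [1] 0.009978496

half_radial_profile(sim$image, fits[1, ])
#> <radial_profile> L1 zone (0, 0): 28 rings, left/right mean 3530.78 / 3530.83
```

All 96 zones are fitted automatically with near-complete edge support; the
recovered half-saturation constant *K* ≈ 1.007 × 10⁵ matches the generator's
10⁵ within 1%, and the median cell-count error after self-calibration is
~1%. (The fitted *I*<sub>max</sub> is ~73% of the generator's, exactly the
area scaling of the 15% cell-free rim; the negative offset *b* is the
paper-minus-wax background difference — see the methods vignette.) The
profile's left/right means agree to ~10⁻⁵ relative, the symmetry expected of
a rotationally symmetric zone.

For a full run (simulate → detect → quantify → calibrate → radial → heat map
→ stack growth → migration) from one YAML config:

```r
run_pipeline("config.yaml", out_dir = "out", seed = 1)
```

or from the shell via the CLI (subcommands `simulate`, `detect`, `quantify`,
`calibrate`, `radial`, `heatmap`, `stack-growth`, `migrate`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","zonestack.R",package="zonestack"))')" \
    run --config config.yaml --out-dir out --seed 1
```

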