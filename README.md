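# ramantag

Hyperspectral Raman analysis of bioorthogonally tagged compounds in single
cells.

Nitrile-substituted drugs (C≡N stretch ≈ 2223 cm⁻¹) and alkyne-tagged
lipid analogs (C≡C stretch ≈ 2115 cm⁻¹) vibrate in the *silent region* of
the cellular Raman spectrum, where endogenous biomolecules are spectrally
quiet. `ramantag` turns raw hyperspectral cubes (H×W pixels × ~1226
wavenumber channels) into per-compartment tag abundances and two-tag
colocalization maps:

- **Pre-processing** — Whittaker–Hayes despiking (modified z-scores of the
  first-difference series, threshold 37), sectioned SNIP background
  correction (100 / 7 / 100 iterations over three merged sections),
  wavenumber calibration against 4-acetaminophen, resampling onto the
  600–3050 cm⁻¹ grid in 2 cm⁻¹ steps.
- **Quantitation** — per-pixel trapezoidal band areas with chord
  subtraction; normalization of the nitrile signal
  `A(CN) / Ā_nuc(789 ± 15 cm⁻¹)` to each cell's nuclear DNA band;
  arsinh display transform; per-compartment distributions.
- **Segmentation** — random-forest pixel classification on eight
  drug-free band-area features; morphological cell-mask extraction
  (threshold 1.5, erode/dilate, largest 8-connected component, hole fill).
- **Peak detection** — smoothing-spline second-derivative band finding
  with relative-height and Δ-prominence rules; treated-vs-control
  differential band reports.
- **Colocalization** — (CN, CC) scatter of normalized areas, kernel
  density mode, four-segment partition (ratio wedge × intensity along the
  central line, boundary just beyond the density mode), back-projection
  onto the pixel grid.
- **DFT conversion** — Raman activities → intensities via
  `I_j ∝ (ν̃₀−ν̃ⱼ)⁴ S_j / (ν̃ⱼ [1−exp(−hcν̃ⱼ/k_BT)])` with frequency
  scaling (0.9626) and 15 cm⁻¹ Lorentzian broadening.
- **SRS corrections** — bilinear pump×Stokes power compensation,
  off-resonance subtraction, silent-window min-max normalization,
  z-projection.
- **Phantoms** — a seeded generator of compartmentalized cell cubes
  (background / matrix / nucleus / lipid droplets) with ground-truth
  class maps and tag loadings, so the whole pipeline is testable without
  any measured data.

## Worked example

Generate a droplet-enriched phantom, train the compartment classifier on a
partial annotation, and run the localization workflow:

```r
library(ramantag)

ph <- make_phantom(phantom_spec(rows = 48, cols = 48,
                                droplet_count = 5, seed = 1))

# partial annotation: 20% of the ground-truth labels
ann <- unclass(ph$truth$class_map)
set.seed(1); ann[sample(length(ann), round(0.8 * length(ann)))] <- 0L

stack <- build_feature_stack(preprocess_cube(ph$cube)$cube)
model <- train_classifier(stack, ann, seed = 1)

res <- run_localization(ph$cube, model)
print(res$distributions$summary, digits = 3)
#>     class    n  mean     sd      se
#> 1  matrix 1099 0.374 0.0828 0.00250
#> 2 nucleus  124 0.185 0.0772 0.00693
#> 3 droplet  145 3.899 0.0935 0.00776
```

The summary gives, per predicted compartment, the mean nitrile band area
normalized by the nuclear DNA reference (here 525.4 counts·cm⁻¹). The
droplet mean exceeds matrix and nucleus by an order of magnitude; the
droplet/nucleus ratio of 21.1 recovers the phantom's constructed loading
ratio of 20 within ~5 %. On a zero-drug control phantom the same summary
gives class means statistically indistinguishable from zero.

The two-tag workflow is one call as well:

```r
res <- run_coloc(ph$cube, model)   # scatter, partition, back-projection
table(res$labels)                  # pixels per colocalization segment
```

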