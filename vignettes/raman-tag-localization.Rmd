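---
title: "Localizing silent-region Raman tags in single cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing silent-region Raman tags in single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramantag)
```

## The problem

Hyperspectral spontaneous Raman microspectroscopy records a full
vibrational spectrum at every pixel of a cell image (here 0.5 µm per
pixel, roughly 1226 channels after resampling). Drugs carrying a nitrile
substituent (C≡N stretch near 2223 cm⁻¹) and lipid analogs carrying an
alkyne (C≡C stretch near 2115 cm⁻¹) vibrate in the *silent region*
(≈1800–2700 cm⁻¹), where endogenous biomolecules contribute essentially
nothing — only a broad water combination band underlies it. This makes
both groups bioorthogonal tags: their band areas report local compound
abundance against a nearly background-free floor.

`ramantag` implements the full analysis chain that turns raw hyperspectral
cubes into per-compartment tag abundances and two-tag colocalization maps,
and ships a synthetic phantom generator so that every stage can be
validated against ground truth without any external data.

## Pre-processing chain

Stages run per pixel, in this order.

**Despiking.** Cosmic-ray spikes are detected on the first-difference
series $d_i = x_i - x_{i-1}$ with the modified z-score
$z_i = 0.6745\,(d_i - \tilde d)\,/\,\mathrm{MAD}(d)$ (raw, unscaled MAD)
and a threshold of 37; flagged channels are replaced by the mean of the
unflagged channels within ±3 channels. Conventions for degenerate input:
$0/0 = 0$ (a constant spectrum is never flagged) and $x/0 = \infty$ (an
isolated spike on a constant floor always is). A consequence worth knowing:
differences of i.i.d. noise with SD $\sigma$ have SD $\sigma\sqrt2$, so a
spike of amplitude $A$ scores $|z| \approx A/(\sigma\sqrt2)$ and the
threshold 37 implies a detection floor of $A \gtrsim 52\,\sigma$. Spikes
at or below ~50 σ are by construction invisible to this statistic; the
test suite states this bound explicitly. The statistic also assumes a
noise floor: on strictly noise-free structured spectra the MAD collapses
to the band-slope scale and band edges are flagged, which is why the
spike-free reference condition in the tests keeps the study noise level.

**Sectioned SNIP background.** The baseline is estimated by plain SNIP
(no log-log-sqrt compression): iterative clipping
$y_i \leftarrow \min\!\big(y_i, (y_{i-p}+y_{i+p})/2\big)$ with the
half-window $p$ growing from 1 to the iteration count, edges clamped.
Three sections are corrected independently — 2600–3150 cm⁻¹ with 100
iterations, 1800–2800 cm⁻¹ with 7, 550–1900 cm⁻¹ with 100 — and merged
with a linear cross-fade across the two overlaps. The gentle 7-iteration
setting in the silent section is the load-bearing choice: with a 2 cm⁻¹
grid the clipping window never exceeds ±14 cm⁻¹, so the narrow
(FWHM ≈ 15 cm⁻¹) tag bands survive nearly intact while the broad
(FWHM ≈ 400 cm⁻¹) water combination band is locally flat on that scale
and leaves with the baseline. Among SNIP variants (increasing vs
decreasing window, with or without the LLS transform) we fixed the plain
increasing-window form; it is isolated in one function and exactly matched
by an independent reference implementation in the tests.

**Calibration and resampling.** The axis is shifted by the mean offset
between known and measured positions of a calibration compound
(a 4-acetaminophen table from the ASTM E1840 Raman-shift standard ships
as editable data). A single global shift is the minimal model consistent
with averaging per-band offsets; wavenumber-dependent warping is out of
scope. Finally each spectrum is linearly interpolated onto the uniform
600–3050 cm⁻¹ grid in 2 cm⁻¹ steps (1226 channels), with no
extrapolation.

## Band quantitation and normalization

A band area is the trapezoidal integral over `center ± half_width`
(default ±15 cm⁻¹, snapped to the grid) of the spectrum minus the *chord*
joining the spectrum values at the window bounds. Chord subtraction
removes any locally linear residual background — the remnant of the water
band in particular — at the price that pure-noise windows integrate to
values scattered around zero, negatives included. That is intended:
truncating at zero would bias compartment means upward.

The nitrile map is normalized per cell by the mean area of the DNA
backbone band (789 ± 15 cm⁻¹, cytosine / O–P–O) over the nucleus pixels,
which cancels instrument throughput and focus differences between cells
and sessions. The normalized ratio is displayed through
$\operatorname{arsinh}(x) = \log(x + \sqrt{x^2+1})$, a log-like
compression that stays defined and odd for negative ratios.

## Segmentation

Eight chord-corrected band-area maps form the pixel feature vector:
789, 1342, 1267, 1100, 1447, 1661, 2850 and 2940 cm⁻¹ (each ±15). The
windows deliberately exclude the drug's own bands (2223, 1618, 1510
cm⁻¹) so segmentation is insensitive to drug loading — the suite verifies
that accuracy changes by < 2 % when loading varies from 0 to 10×. A
random forest (100 trees, unrestricted depth, seeded) is trained on the
labeled pixels of partially annotated images and predicts each pixel
independently; no spatial features enter, so predictions are
permutation-equivariant over pixels. Forest hyperparameters and feature
scaling (none) were design choices recorded in the model object.

The cell mask thresholds the class map at 1.5 (anything that is not
background), applies one 3×3 erosion and one 3×3 dilation, keeps the
largest 8-connected component (discarding partly imaged cells at the
border), and fills interior holes by border flood fill. The operation is
idempotent, and a manual override mask can be ANDed in to repair
misclassified background.

## Peak detection and differential bands

Band maxima are found on the max-1-normalized spectrum as local minima of
the second derivative of a fitted smoothing spline (negative minima
only), kept when their curvature magnitude reaches 2 % of the global
maximum and when the normalized spectrum recedes by at least Δ = 0.01 on
both sides of the associated crest. Positions are read off a 10×-refined
evaluation grid.

Smoothness selection is the one genuinely open design point. A
FITPACK-style absolute residual budget is tied to the intensity scale of
the data it was tuned on and would break the contract that detection is
invariant under positive rescaling of the spectrum; the default is
therefore generalized cross-validation, which is scale-free, and a
numeric residual budget (interpreted on the normalized spectrum) remains
available in `peak_config()`. R's smoothing splines are cubic; the
quartic-spline variant of the original tuning is not available and the
cubic fit's piecewise-linear second derivative localizes band centers to
within one 2 cm⁻¹ channel, which is inside every tolerance used here.

Treated-minus-control reporting matches peaks between two spectra on a
common axis with a 10 cm⁻¹ tolerance; a zero tolerance would count the
1–2 cm⁻¹ jitter of independent re-detections of the same band as "new",
which the tests document.

## Two-tag colocalization

Within the cell mask, every pixel becomes a point
$(x, y) = (A_{CN}/\bar A_{nuc},\; A_{CC}/\bar A_{nuc})$. Points with a
negative coordinate are excluded from the scatter but kept for display
(they are marked distinctly in the back-projection). The density mode of
the retained cloud is located on a 256×256 kernel-density grid
(normal-reference bandwidths); the mode is computed after the negativity
exclusion. The central line through the origin with slope $s = y^*/x^*$
splits the cloud by CC/CN ratio, and the projection
$t = (x + s\,y)/\sqrt{1+s^2}$ splits each wedge at
$t_0 = 1.05\,t_{mode}$ — just beyond the point of highest density.
Boundary points go to the lower-ratio / lower-intensity segment. The four
segments partition the retained points exactly, the labeling is invariant
under a common positive rescaling of both maps, and back-projection is
bijective with the point list. The trapezoid corners of the published
construction are not printed anywhere, so the geometry is parameterized
(slope, band factors, $t_0$ factor) with these defaults.

## Activity-to-intensity conversion

Quantum-chemistry codes report Raman *activities* $S_j$ (Å⁴ amu⁻¹) per
normal mode. After scaling the harmonic frequencies by the empirical
factor 0.9626, intensities follow the fourth-power scattering law with
Boltzmann occupation,

$$I_j \;\propto\; \frac{(\tilde\nu_0-\tilde\nu_j)^4\, S_j}
  {\tilde\nu_j\,\bigl[1-\exp(-h c \tilde\nu_j / k_B T)\bigr]},$$

with $\tilde\nu_0 = 19\,455.3$ cm⁻¹ (514 nm excitation) and
$T = 298.15$ K; 2018 CODATA constants are shipped. An alternative
$\tilde\nu_0^4$ prefactor convention is selectable. The stick spectrum is
broadened with unit-peak-height Lorentzians of FWHM 15 cm⁻¹ (unit-area
selectable) and max-normalized. Normalization makes the result invariant
to a common scaling of all activities, and feeding the broadened spectrum
back into the peak finder recovers all mode positions to within 2 cm⁻¹
when modes are well separated.

## SRS corrections

Stimulated Raman loss is bilinear in pump and Stokes power, so frames are
rescaled by $(P^{ref}_{p} P^{ref}_{S})/(P_p P_S)$ against the first frame
(a pump-only model is selectable; the bilinear default reflects the
physics). Off-resonance frames (2500 cm⁻¹) are subtracted pixelwise with
negatives preserved; λ-scan spectra are min-max normalized over
2050–2300 cm⁻¹; z-stacks are collapsed by max (or mean) projection.

## The phantom generator

The generator emulates exactly the statistical structure the analysis
assumes: an elliptical cell on background, a nucleus strictly inside it,
lipid droplets placed by seeded rejection sampling inside the cell and
outside the nucleus, per-compartment Lorentzian band dictionaries
(DNA 789 cm⁻¹ in the nucleus, CH₂ 2850 cm⁻¹ dominating droplets, protein
bands in the matrix), the drug band set (2223, 1618, 1510, 1255 cm⁻¹ at
relative heights 1 : 0.35 : 0.3 : 0.15, 20 counts per loading unit at the
nitrile), an alkyne band at 2115 cm⁻¹, a broad water band
(2150 cm⁻¹, FWHM 400, 30 counts), a low-order polynomial baseline,
additive i.i.d. Gaussian noise, and optional seeded single-channel
spikes. Default per-compartment drug loadings are droplet 10, matrix 1,
nucleus 0.5 (constructed droplet/nucleus ratio 20); an optional
perinuclear ring adds drug and/or alkyne loading to matrix pixels near
the nucleus for colocalization experiments. All amplitudes are invented
but chosen at realistic cellular Raman magnitudes; no published
enhancement factor exists for the in-droplet enrichment, so these
loadings are study conditions, not measured values.

What the phantom does *not* emulate — and hence what green tests do not
establish about real data: optical blur (compartment boundaries are
hard), Poisson photon statistics (noise is additive Gaussian),
autofluorescence baselines beyond a smooth polynomial, spectral overlap
from unmodeled cellular species, and 3-D sectioning. Segmentation
accuracies near 1.0 on phantoms therefore witness the correctness of the
plumbing, not expected field performance.

## Problem sizes and numerics

The validation experiments use 48×48 px phantoms (64×64 for the despiking
study) with ~1300 raw channels, sizes chosen so each experiment completes
in seconds while keeping several hundred pixels per compartment class.
Windows snap to the nearest on-grid channel; SNIP sections must contain
more than twice their iteration count in samples; interpolation never
extrapolates; the nuclear reference must be strictly positive, and a
non-positive reference is an error rather than a silent NaN. All
randomness (phantom geometry, noise, spikes, annotation subsampling,
forest training) is seeded, and identical seeds reproduce outputs
bit-exactly.
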