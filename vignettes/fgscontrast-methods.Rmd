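---
title: "Methods: contrast metrics and border localization for paired-modality fluorescence imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast metrics and border localization for paired-modality fluorescence imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgscontrast)
```

## The problem

In fluorescence-guided surgery a targeted dye accumulates in tumor tissue
and an intraoperative camera visualizes it. Whether a second spectral
window (e.g. imaging the SWIR emission tail of an NIR dye with an InGaAs
camera) improves tumor delineation is an empirical question that must be
answered on tissue, against pathology. The unit of analysis is a tissue
slice imaged by both systems, with the tumor region segmented on the
H&E-stained section. Because the two cameras view the slice from slightly
different geometries, the images must first be brought into a common frame;
all contrast metrics are then computed per modality on identical regions.

This vignette records the models, parameter choices and numerical
conventions the package commits to, and what its synthetic tests do and do
not demonstrate about real data.

## Registration

Correspondence between frames is established from user-clicked control
points. The package fits the least-squares similarity transform — isotropic
scale $s$, rotation $\theta$, translation $t$, mapping moving to fixed
coordinates as $y = sR(\theta)x + t$ — in closed form (the
Procrustes/Umeyama solution), which is exact, deterministic, and matches
the similarity-transformation registration used in practice for this task.
Reflections are disallowed (the determinant is forced positive): two
cameras viewing the same physical slice cannot produce mirrored views.
Modality B is always resampled into modality A's frame so that masks and
line annotations live in a single reference frame.

Conventions: coordinates are `(row, col)`, **1-based**, with pixel centers
at integer coordinates (the natural convention in R; every CSV the package
reads or writes uses it). Resampling is bilinear by default; pixels whose
pre-image falls outside the moving image are set to the `NA` sentinel and
excluded from every downstream statistic, so registration never biases an
MFI. Domain membership is tested with a $10^{-9}$-pixel tolerance so that a
numerically-identity transform does not shed boundary pixels.

## ROI metrics

For a region of interest, `roi_stats()` returns the mean fluorescence
intensity (MFI), the **population** standard deviation (divisor $n$), pixel
count and extremes. ROIs here contain thousands of pixels, so the $n$ vs
$n-1$ distinction is negligible; fixing the population form keeps the
analytic test oracles exact and matches the plain "standard deviation" of
the metric definitions.

- $\mathrm{TBR} = \mathrm{MFI}_{tumor} / \mathrm{MFI}_{background}$.
  Scale-invariant, not offset-invariant.
- $\mathrm{aCNR} = (\mathrm{MFI}_{tumor} - \mathrm{MFI}_{background}) /
  (2\sigma_{background})$. The factor two on the background SD makes the
  measure conservative against noise; aCNR is invariant to positive affine
  intensity maps. A pixel at exactly background mean $+2\sigma$ has
  aCNR $= 1$.
- $\mathrm{SNR(dB)} = 20\log_{10}((\mathrm{MFI}_{signal} -
  \mathrm{MFI}_{control})/\sigma_{control})$, with detectability defined as
  SNR **strictly** greater than 9.5 dB — the 3σ rule
  ($20\log_{10} 3 = 9.54$ dB). A non-positive excess is flagged
  not-detectable (`NA`) rather than mapped to a number.
- Background-image subtraction clips at zero: negative fluorescence is
  unphysical, and residual negative values would shift the downstream
  min–max normalization.

## Line-based border analysis

Lines are drawn through tumor tissue perpendicular to the pathology tumor
edge. Each line is widened to an 11-pixel sub-image (bilinear samples at
1-pixel steps along the line and integer perpendicular offsets) and
collapsed back to one pixel by a Gaussian-weighted mean across the width.

Choices where the procedure itself is underdetermined:

- **Collapse kernel**: `sigma_perp = width/6` (≈ 1.83 px for width 11), so
  the ±3σ support of the kernel spans the full width. Only a "Gaussian
  mean" is specified by the underlying procedure; the width/6 rule is this
  package's default and is configurable.
- **Along-line sampling**: 1-pixel steps with bilinear interpolation, which
  is exact on locally affine intensity fields and alias-free on oblique
  lines.
- **Line means**: the per-line mean TBR and mean aCNR average over **all**
  positions of the line (tumor and background); a tumor-only scope is
  available via `scope = "tumor"`.
- **AUC abscissa**: the trapezoidal AUC of the aCNR curve over the
  tumor-labeled run uses **pixel** units, so a constant aCNR of $c$ over
  $k$ tumor pixels gives $c(k-1)$. Reported AUC magnitudes of order 1–30
  at aCNR of order 1 are consistent with tens of pixels, not millimetres.
- **aCNR = 1 crossing, multiple-crossing rule**: scanning from the tumor
  end, the crossing is the *last* transition from aCNR > 1 to aCNR ≤ 1 at
  or before the first background sample — noise spikes in the far
  background must not redefine the border. If the profile is still above 1
  when it enters the background, the first subsequent down-crossing
  (closest to the border) is used. The crossing position is linearly
  interpolated between the bracketing samples; a profile that never
  exceeds 1 has no crossing, which is a valid outcome and is what the
  positive/negative agreement statistics count.
- The ground-truth border position is the midpoint between the last sample
  on one side of the mask boundary and the first on the other (±half a
  pixel of quantization).

Four lines per slice is a study-design convention, not a library
constraint; `write_study_bundle()` mirrors it as a default.

## Pixel-level agreement

Paired in-mask, in-frame pixels of the two registered modalities are
min–max normalized per modality, then compared by OLS simple linear
regression $r^2$, Bland–Altman bias and SD of differences (oriented
B − A, with limits of agreement at bias ± 2·SD), and the percentage of
tumor pixels at or below (inclusive) the maximum background intensity — a
rank statistic, invariant to any strictly increasing intensity transform.

## Phantom tools

- **Tube FWHM**: the mean cross-section perpendicular to a dye-filled tube
  is normalized to its own maximum; FWHM is measured between
  linearly-interpolated half-maximum crossings, with the baseline assumed
  near zero. Profiles whose above-half-max region is not connected are
  rejected rather than guessed at. `filter_tradeoff()` reports the
  percentage FWHM change between two filter configurations at matched
  depths.
- **Sensitivity series**: each well's SNR(dB) against the zero-concentration
  control, with the strict > 9.5 dB rule; the reported detection limit is
  the smallest concentration detectable together with every larger one (a
  monotone cut), so an isolated spurious pass below non-detectable wells is
  not a limit. The visual reflection-exclusion practice is replaced by this
  quantitative rule, with reflection pixels excludable via the ROI mask.
- **Spectral correction**: the lamp's calibration spectrum is fitted by a
  two-parameter (temperature, scale) wavelength-form Planck curve; gray
  emissivity is assumed. The fit profiles the scale out in closed form and
  minimizes over temperature with a coarse log-spaced grid plus
  golden-section refinement — deterministic, no starting value. A fit whose
  optimum pins to the search boundary, or that explains less than half of
  the spectral variance (e.g. a flat spectrum, which has no Planck shape),
  is reported as non-convergent. The correction curve is the fitted Planck
  curve divided by the *recorded* spectrum; multiplying raw spectra by it
  removes the detection-chain response.

## The synthetic-data generator

`slice_phantom_spec()` defines a paired scene with exactly known ground
truth: an elliptical tumor of elevated mean on a background, per-modality
Gaussian PSF blur, additive Gaussian noise, an optional smooth additive
autofluorescent field on modality B, and a similarity-transform
misalignment applied to modality B as the **last** synthesis step — so the
true registration transform is exactly the inverse of the specified
misalignment and registration has an exact oracle. The B scene is
synthesized on a padded canvas so the misaligned camera still sees a full
frame.

Default conditions (chosen once, to sit at the magnitude of published
clinical medians for penile squamous cell carcinoma):

| parameter | default | rationale |
|---|---|---|
| image shape / pixel pitch | 200×200 px, 0.1 mm/px | ~2 cm field of view at macro-imaging resolution |
| tumor ellipse | semi-axes 60×52 px | ≈ 10⁴ tumor pixels, ≈ 3×10⁴ background pixels |
| means A (tumor/bg) | 0.143 / 0.100 | TBR 1.43, the NIR-modality whole-slice median scale |
| means B (tumor/bg) | 0.125 / 0.100 | TBR 1.25, the SWIR-modality counterpart |
| noise SD A / B | 0.0358 / 0.0145 | whole-slice aCNR of 0.60 and 0.86 respectively |
| blur σ A / B | 2 / 1 px | stronger scattering blur for the shorter-wavelength modality |
| autofluorescence B | 0 (off) | set it above the B contrast (e.g. 0.05) to reproduce the failure mode in which smooth background autofluorescence overwhelms the off-peak signal, as seen in strongly perfused tissue |
| misalignment | scale 1.02, rot 0.03 rad, (3.5, −2.5) px | small realistic two-camera offset |

Intensities are kept inside [0, 1] so images survive the float-TIFF disk
round trip; writing clips to [0, 1] (like a physical sensor), and the
in-memory floats remain the ground truth. The autofluorescent field is
Gaussian-smoothed white noise standardized to unit SD and scaled by the
amplitude — the simplest low-frequency structured background that
reproduces the overwhelmed-signal failure mode; its spatial statistics are
a stand-in, not a claim about tissue physics.

What the generator does **not** emulate: optical light transport,
camera-specific noise (dark current, fixed-pattern), 3-D tissue geometry,
dye pharmacokinetics, or irregular (non-elliptical) tumor margins. Passing
the synthetic recovery tests therefore demonstrates the correctness of the
estimators and of the pipeline plumbing, not clinical performance.

## Calibration conditions for the recovery tests

The estimator-calibration tests (200 seeded slices for TBR/aCNR recovery)
run the generator with blur 0 and identity misalignment: PSF blur mixes the
classes at the tumor boundary and bilinear warping averages noise, so the
analytic targets $\mu_t/\mu_b$ and $(\mu_t-\mu_b)/(2\sigma)$ are exact only
for the unblurred, unwarped scene. Border-localization tests use 500
synthetic step-contrast lines (pixel-level step 0.03 over noise SD 0.01,
blur σ = 1 px, ≥ 20 positions per side), where the collapsed-profile tumor
aCNR is ≈ 4; the median localization error is required to be below one
pixel pitch, and it degrades as the contrast approaches aCNR = 1. The
Wilcoxon size check uses 2,000 null simulations at n = 20. These problem
sizes keep the full suite around ten seconds while leaving Monte-Carlo
standard errors small enough for 3-SE assertions.

## Study-level statistics

Reporting is always nonparametric — median, IQR and paired two-sided
Wilcoxon signed-rank tests — because fluorescence-intensity metrics of this
kind are generally not normally distributed; no normality pre-test branch
is implemented. Quartiles use R's default linear-interpolation (type 7,
"inclusive") method; IQR values depend on this choice, so it is fixed.
Zero differences are dropped before the signed-rank test (with counts
reported); the exact distribution is used for ≤ 25 remaining pairs — note
that tied |differences| force R's normal approximation with continuity
correction — and the approximation above that. The 0.05 significance
threshold is reported, never used to filter rows. `run_study()` is
deterministic given its inputs; failing slices are skipped with recorded
reasons, and an all-failed study is an error.

## Known limitations

- The aCNR = 1 border criterion presumes a single tumor→background
  transition per line; infiltrative margins with multiple transitions are
  rejected by the labeling step rather than guessed at.
- FWHM assumes a near-zero baseline; profiles with substantial pedestal
  require background subtraction first.
- The black-body fit assumes gray emissivity; strongly wavelength-dependent
  emissivity would bias the fitted temperature and hence the correction.
- Registration is global and similarity-only; tissue deformation between
  acquisitions is not modeled.
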