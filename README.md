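# fgscontrast

Quantitative comparison of paired fluorescence images of the same tissue
slice acquired with two imaging systems — typically a near-infrared (NIR)
camera and a shortwave-infrared (SWIR) camera imaging the emission tail of
the same NIR dye. The package is aimed at fluorescence-guided-surgery
researchers who need to decide, against the pathology ground truth, whether
a second imaging modality actually improves tumor-to-background contrast
and tumor-border delineation.

## What it computes

Given two co-registered images and an H&E-derived tumor mask, the package
reports the field's standard contrast metrics:

- **TBR**, tumor-to-background ratio: `TBR = MFI_tumor / MFI_background`,
  where MFI is the mean fluorescence intensity over a region of interest.
- **aCNR**, adapted contrast-to-noise ratio:
  `aCNR = (MFI_tumor − MFI_background) / (2·σ_background)` — the background
  SD is scaled by two to make the measure robust to noise. A pixel exactly
  two background SDs above the background mean has aCNR = 1.
- **SNR(dB)** `= 20·log10((MFI_signal − MFI_control)/σ_control)`, with the
  3σ detectability rule: a signal is detectable iff SNR > 9.5 dB
  (20·log10(3) ≈ 9.54 dB).
- **Line-based border analysis**: lines drawn perpendicular to the tumor
  edge are widened to 11 pixels, collapsed with a Gaussian mean, and turned
  into per-pixel TBR/aCNR profiles; the position where the aCNR profile
  crosses 1 estimates the tumor border, and its absolute distance to the
  pathology border is reported, together with the AUC of the aCNR curve
  over tumor pixels.
- **Pixel-level agreement**: OLS r², Bland–Altman bias (SD) and the
  percentage of tumor pixels at or below the maximum background intensity.
- **Phantom characterization**: FWHM of tube-phantom cross-sections,
  dilution-series sensitivity limits under the 3σ rule, and black-body
  spectral-response correction from a calibrated halogen lamp.

Registration between the two camera frames uses a closed-form least-squares
similarity transform (isotropic scale + rotation + translation, no
reflection) fitted to user-supplied control-point pairs; modality B is
resampled into modality A's frame with out-of-frame pixels marked `NA` and
excluded from every statistic.

A synthetic-scene generator (`slice_phantom_spec()`, `generate_slice_pair()`,
`generate_tube_image()`, `generate_well_series()`, `generate_lamp_spectrum()`)
produces paired images, tube phantoms, well series and lamp spectra with
exactly known ground truth, so the whole pipeline is testable end to end
without clinical data.

## Worked example

```r
library(fgscontrast)

# a synthetic 5-slice study with known ground truth, written to disk
d <- file.path(tempdir(), "demo")
write_study_bundle(d, n_slices = 5, seed = 42)
res <- run_study(file.path(d, "manifest.csv"))
print(res$comparison, digits = 3)
```

```
                                         metric  n median_a   q1_a    q3_a median_b   q1_b    q3_b  p_value
1                        TBR whole tissue slice  5   1.4178  1.411  1.4199    1.244  1.243  1.2465 6.25e-02
2                       aCNR whole tissue slice  5   0.5843  0.577  0.5862    1.555  1.544  1.5597 6.25e-02
3                                 TBR over line 20   1.1996  1.187  1.2178    1.122  1.117  1.1249 1.91e-06
4                                aCNR over line 20   0.9527  0.828  1.0980    1.523  1.410  1.7079 1.91e-06
5                                      AUC aCNR 20  47.0048 40.634 53.9786   74.745 69.596 84.6109 1.91e-06
6 Absolute distance tumor border to aCNR=1 (mm) 20   0.0539  0.033  0.0849    0.019  0.011  0.0372 1.02e-03
```

Each row compares the two modalities on one metric: median and IQR per
modality over the paired slices (n = 5) or lines (n = 20), with a paired
two-sided Wilcoxon signed-rank p-value. The generator's modality A has a
true whole-slice TBR of 1.43 (the measured 1.42 reflects PSF blur mixing
classes at the boundary), and the aCNR = 1 crossing localizes the true
border to well under one 0.1-mm pixel. `res$agreement` reports how often
modality B finds an aCNR = 1 crossing on lines where modality A does
(here: positive agreement 100%; negative agreement undetermined because A
found a crossing on every line).

Single metrics are available directly:

```r
sl <- generate_slice_pair(slice_phantom_spec(seed = 42))
ts <- roi_stats(sl$image_a, sl$tumor_mask)
bs <- roi_stats(sl$image_a, !sl$tumor_mask)
tbr(ts, bs)    # 1.424
acnr(ts, bs)   # 0.589
```

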