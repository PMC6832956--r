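# ramanpollen

High-throughput, label-free pollen identification from bright-field
microscopy and Raman spectroscopy, in R.

Automated palynology needs to identify large numbers of pollen grains
consistently, including taxa whose morphology is too similar for
image-based classification. A high-throughput screening Raman platform
solves this by locating particles in bright-field frames, steering the
laser to each grain, and classifying the acquired spectra by their
molecular fingerprint. `ramanpollen` implements the computational side of
that workflow for spectroscopists and palynologists:

* **Bright-field localization** — 8-bit conversion, Otsu histogram
  thresholding (dark foreground), particle size filtering, fill-hole +
  dilation morphology, 8-connected blob analysis, pixel-to-stage affine
  mapping, Gaussian autofocus fitting and slide tilt-plane correction.
* **Spectral preprocessing** — wavenumber calibration against a Raman
  shift standard (4-acetaminophenol band table included), white-lamp
  intensity calibration, width-gated cosmic spike removal, extended
  multiplicative signal correction (EMSC), area normalization, and
  region cropping, with per-spectrum provenance and no silent drops.
* **Chemometric identification** — growth-habit screening by
  average-linkage hierarchical clustering under the Minkowski (p = 5)
  distance with cophenetic validation; per-habit taxonomy by PCA (9
  components) feeding a one-vs-one error-correcting-output-codes SVM
  with Gaussian kernels, stratified 10-fold cross-validation, confusion
  matrices with per-class sensitivity and positive predictive value, and
  t-SNE score visualization with class medians.
* **Synthetic data** — a seeded generator for ground-truthed bright-field
  frames, class-structured Raman spectra (37-class pollen taxonomy
  template: 4 growth habits, 18 families, 36 genera), and calibration
  fixtures, so the whole pipeline is testable end to end with known
  truth.

## The model in brief

A measured spectrum is treated as

```
y(nu) = b * r(nu) + c_w * w(nu) + p0 + p1*nu + p2*nu^2 + spikes + noise
```

where `r` is a background-corrected reference spectrum, `w` a water
spectrum, and the quadratic captures fluorescence. EMSC fits the
coefficients by ordinary least squares and inverts to the reference
scale, `(y - interferents - polynomial) / b`. Classification operates on
area-normalized corrected spectra over the fingerprint (758–1800 cm⁻¹)
and high-wavenumber (2800–3045 cm⁻¹) windows; habit screening clusters
per-species mean fingerprint spectra with
`d(x, y) = (Σ|x_i − y_i|^5)^(1/5)` and average linkage.

## Worked example

```r
library(ramanpollen)

profiles  <- separable_profiles(4, separation = 0.25)
design    <- spectrum_design(n_per_class = 40, noise_sd = 0.05, seed = 1)
dataset   <- generate_dataset(profiles, design)
processed <- preprocess_pipeline(dataset)
result    <- run_taxonomy(processed, "herb",
                          taxonomy_config(train = train_config(25, 5, seed = 1),
                                          tsne_iter = 100))
print(result)
print(result$confusion)
```

```
<taxonomy_result> habit 'herb': 4 classes, train 100 / test 60
  cumulative variance (9 PCs): 57.94%
  CV misclassification: 0.00%  test accuracy: 100.00%
<confusion_matrix> 4 classes, n = 60, accuracy = 100.0%
          predicted
actual     genus_01 genus_02 genus_03 genus_04
  genus_01       15        0        0        0
  genus_02        0       15        0        0
  genus_03        0        0       15        0
  genus_04        0        0        0       15
sensitivity (%): genus_01 100.0, ..., genus_04 100.0
PPV (%): genus_01 100.0, ..., genus_04 100.0
```

Four synthetic pollen classes whose band amplitudes differ by five times
the channel noise are generated, background-corrected, and classified:
the nine retained principal components carry 57.9% of the spectral
variance here (most of the rest is per-spectrum noise), cross-validation
on the 100 training spectra is error-free, and all 60 held-out spectra
are assigned to the correct genus.

The same pipeline is available from the shell via the installed
`exec/ramanpollen` script (`simulate`, `detect`, `preprocess`, `hca`,
`taxonomy`, `analyze`, `config` subcommands driven by a YAML
configuration).

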