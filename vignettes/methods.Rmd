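---
title: "Methods: bright-field localization and Raman chemometrics for pollen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bright-field localization and Raman chemometrics for pollen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ramanpollen` implements the computational core of a high-throughput
screening Raman workflow for pollen: particles are located in
bright-field frames, their coordinates converted to stage positions,
and the Raman spectrum acquired at each grain is preprocessed and
classified. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data module does and does
not emulate.

## Bright-field localization

A field of view is converted to 8-bit grayscale (min–max rescale; RGB
reduced by Rec. 601 luminance first), thresholded from its 256-bin
histogram, size-filtered, morphologically cleaned, and decomposed into
blobs.

**Thresholding.** The histogram-based threshold is the Otsu criterion:
the cut maximizing the between-class variance of the two intensity
classes. It is deterministic; among equal-variance cuts the lowest is
taken. Foreground is the *darker* class, because in transmitted-light
bright field particles absorb and the background sits near the top of
the intensity range. A single-valued histogram is flagged degenerate and
yields an empty foreground rather than an error.

**Size filter.** Connected components (8-connectivity throughout) with
pixel areas outside `[min_area, max_area]` are removed. Defaults are the
areas of 10–100 µm diameter disks at the frame's pixel size — the
typical range of pollen grains — and are configurable.

**Morphology.** Both cleanup stages are iterative 3×3 logical-or
thickening: `fill_iterations` (default 3) passes close interior voids
(pollen often image with bright centers), then `dilate_iterations`
(default 1) stabilizes outlines. The operation is monotone — foreground
is never removed — and zero iterations is the identity. Because
thickening is symmetric it does not bias centroids of convex particles.

**Blob analysis.** One blob per 8-connected component; the centroid is
the unweighted mean of member pixels in 0-based coordinates (x = column,
y = row, origin top-left); blobs sort by centroid (y, x). Stage
coordinates are `linear %*% (x, y) + offset + frame_index * frame_pitch`
(µm), with the affine transform required to be invertible.

**Autofocus and tilt.** The focus metric (variance of the Laplacian, a
standard sharpness figure; the choice is ours, any unimodal metric
works) is sampled along z and fitted with a Gaussian plus offset by
Levenberg–Marquardt least squares; the fitted center is the best focus.
A fit that does not converge or whose center leaves the sampled range —
as with a monotone profile — is a focus failure, not a silent
extrapolation. Slide tilt is a least-squares plane `z = a·x + b·y + c`
through sampled best-focus points; collinear points are rejected.

## Spectral preprocessing

Stages run in a fixed order: wavenumber calibration, intensity
calibration, cosmic spike removal, EMSC background correction, area
normalization. The order matters — normalizing before background
correction would normalize the background too — and is recorded in a
per-run provenance log together with per-spectrum spike counts, EMSC
coefficients, and any drops with reasons.

**Wavenumber calibration.** A 4-acetaminophenol spectrum on the camera
pixel axis is reduced to sub-pixel peak positions (local maxima refined
by local quadratic interpolation), matched to the literature band table
(the ASTM E1840 acetaminophen list is bundled), and fitted with a
polynomial pixel-to-wavenumber map (degree 3 by default). Matching first
pairs the most prominent maxima to the table in axis order — both
sequences are monotone — then re-matches all maxima to the nearest table
entry within a tolerance (10 cm⁻¹) under the provisional fit and refits.
The fitted map must be strictly increasing; the residual RMS is
reported. After calibration spectra are linearly interpolated onto a
uniform grid so that all spectra share one axis, which EMSC requires.

**Intensity calibration.** Correction factors are certified/measured
white-lamp ratios per channel; channels with non-positive measured
intensity are masked (factor 1), and more than 20% masked channels is a
calibration error.

**Cosmic spike removal.** Spikes are narrow, tall excursions. Channels
whose positive residual from a running-median baseline (window 7)
exceeds 8× a robust scale are candidates; a candidate's *feature width*
is the extent of the contiguous excursion above a quarter of that
threshold, and only features narrower than 3 channels are replaced (by
linear interpolation of the flanking clean channels). Two numerical
details matter. First, the robust scale is the MAD of the residual
*floored at 2% of the spectrum's dynamic range*: over monotone stretches
the running-median residual is exactly zero, so in low-noise spectra the
raw MAD collapses and smooth band curvature would read as spikes;
cosmic events (tens of times the local amplitude) sit far above the
floor. Second, unflagged channels are bit-identical to the input — the
operation is surgical by construction.

**EMSC.** Each spectrum is regressed by ordinary least squares on a
reference spectrum, a water interferent, and a quadratic polynomial in
the axis rescaled to [−1, 1] (for conditioning):

$$y = b\,r + c_w\,w + p_0 + p_1\nu + p_2\nu^2 + \varepsilon$$

and corrected as `(y − c_w w − p0 − p1 ν − p2 ν²)/b`. On a noise-free
mixture the correction returns `r` exactly (the design is full rank by
construction and checked). A fitted `|b|` below a floor (10⁻⁶) marks a
degenerate fit; the spectrum is dropped with a logged reason. The
default reference is the per-channel median of the spike-cleaned
dataset with a quadratic trend removed and shifted to be nonnegative;
the shift keeps the reference's integrated area away from zero, which
keeps the subsequent area normalization well conditioned (an unshifted
detrended median has near-zero sum, making normalized spectra unstable).
A user-supplied reference takes precedence and is the right choice
whenever a background-corrected spectrum of the target material exists.
The water interferent is a closed-form broad-band curve (OH bending near
1640 cm⁻¹ plus the low-wavenumber tail of the OH stretch envelope);
computing it in code rather than bundling a measured curve keeps the
package text-only and deterministic, at the cost of spectroscopic
realism that the correction itself does not require.

**Normalization and cropping.** Area normalization divides by the plain
sum over the normalization region (full axis by default). "Area" is
ambiguous between a sum and a trapezoidal integral; on a uniform grid
they differ by a constant factor that the normalization itself absorbs,
so the simpler contract is used. Cropping retains channels inside
closed bounds; an empty overlap is an error.

## Chemometrics

**Growth-habit screening.** Per-species mean spectra over the
fingerprint region (758–1800 cm⁻¹) are clustered by average-linkage
agglomeration under the Minkowski distance with exponent 5, which
weights the largest channel-wise differences more heavily than
Euclidean distance. Dendrogram fidelity is the cophenetic correlation
coefficient (Pearson correlation between original and cophenetic
distances). The tree is cut into four flat clusters and each cluster
mapped to the majority growth habit of its members, ties resolving to
the lexicographically first habit; the mapping is scored with a
confusion matrix.

**Per-habit taxonomy.** Within one habit, spectra are cropped to the
concatenated fingerprint and high-wavenumber (2800–3045 cm⁻¹ by
default; the upper window's exact bounds are a package choice) regions,
mean-centered PCA retains 9 components (with the cumulative explained
variance reported), and a support vector machine classifies the scores.
The multiclass scheme is one-vs-one coding over an error-correcting
output code matrix: `k(k−1)/2` Gaussian-kernel binary learners, each
with its own kernel scale (per-learner median heuristic,
`gamma = 1/(2·median²)` of the pairwise training distances, since no
scale is prescribed); decoding minimizes the Hamming distance to the
code rows over non-zero entries — equivalently, majority voting — with
ties resolved to the lowest label order. Per class, 100 training
samples are drawn without replacement (seeded); the remainder is the
held-out test set, and train/test disjointness is recorded in the model
object. "Ten-fold leave-one-out cross-validation" is a contradiction in
terms; the implementation performs stratified 10-fold cross-validation
(folds balanced within each class to within one sample), which matches
the protocol of splitting the training scores into ten groups, modeling
on nine and predicting the tenth. Confusion matrices report per-class
sensitivity (row-wise recall), positive predictive value (column-wise
precision), and overall accuracy.

**t-SNE.** Training scores are embedded in 2-D for visualization only;
the embedding never feeds classification. No Barnes–Hut t-SNE
implementation is available to this package, so the exact O(n²)
gradient (the limit of Barnes–Hut as its accuracy parameter goes to
zero) is implemented directly, with standard early exaggeration (factor
12 for 100 iterations), momentum scheduling (0.5 → 0.8 at iteration
250), and a seeded Gaussian initialization; the score sets embedded
here are a few hundred points, for which exact gradients are cheap.
Per-class medians are component-wise.

## The synthetic-data module

The generator is a first-class, tested component: every downstream
guarantee is verified against its ground truth.

A class profile is a set of Gaussian bands (center, amplitude, width),
a polynomial fluorescence baseline, and a water weight. A spectrum is
`scatter × Σbands + baseline + water + noise + spikes`, with the
multiplicative scatter drawn once per spectrum (mean 1, sd 0.15),
additive Gaussian channel noise (default sd 0.01 against band
amplitudes of order 0.5–1), and Poisson-count cosmic spikes (rate 0.05
per spectrum) of 10–100× the local amplitude on single channels. The
exact additive decomposition is retained alongside each spectrum, so
tests can assert ground-truth closure channel by channel. The default
axis spans 600–3100 cm⁻¹ in 1200 channels, covering the fingerprint
region and the CH-stretch band near 2851 cm⁻¹; the true instrument's
axis extent is not public, so these are deliberate stand-ins.

The 37-class template instantiates a realistic pollen taxonomy — 16
grass, 5 herb, 5 shrub (two congeneric species), 11 tree classes; 36
genera, 18 families — with bands at canonical pollen Raman positions
(nucleic acid 783, phenylalanine 1004, lipids 1065/1304/1441/1750/2851,
sporopollenin aromatics 1173–1637, amide I 1660 cm⁻¹). Each habit
emphasizes its own subset of bands over a shared signature, so
unsupervised clustering can recover habits; species superimpose a
smaller fixed trigonometric amplitude modulation (depth 0.25), so
supervised models can resolve them. The patterns are deterministic
functions of the class index — no randomness enters profiles.

Bright-field frames place non-overlapping dark disks (intensity 0.25 on
a 0.88 background) by rejection sampling with bounded retries, with
optional central voids (exercising hole filling), an optional linear
illumination ramp, and pixel noise.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: detector nonlinearity and etaloning,
wavenumber-dependent noise, Lorentzian/Voigt band shapes and band-width
variation between taxa (band shape is pluggable but Gaussian by
default), biochemical amplitude covariance between bands, textured or
aspherical particles, clumping, and out-of-focus blur. Results on
synthetic data bound algorithmic correctness, not instrument
performance.

## Problem sizes and tolerances

The test suite works at desk scale by choice: parameter-recovery runs
use 4 classes × 130 spectra (100 training per class per the protocol,
the rest held out) over a five-point separation-to-noise sweep
(5, 2, 1, 0.5, 0.25) with ten seeds per point; detection is verified on
100 seeded noise-free frames with disk separation at least four times
the maximum radius (centroid tolerance 1 px); clustering is checked
against a brute-force average-linkage oracle up to n = 12 items (height
tolerance 10⁻⁹); EMSC exact recovery is asserted to 10⁻⁶ per channel;
chance-level cross-validation uses 20 permutations of 4 balanced
classes. The acceptance script regenerates a full 37-class study (130
spectra per class) and reports the quantities it computes; its t-SNE
runs 150 iterations to keep the embedding step proportionate.

## Known limitations

* The exact t-SNE becomes slow beyond a few thousand points; embed
  subsamples there.
* The connected-component labeling is vectorized R over pixel
  adjacency; frames far larger than ~10⁶ pixels will feel it.
* Wavenumber calibration assumes the standard's bands are the dominant
  local maxima; heavily contaminated standards need manual peak tables.
* The median-reference EMSC default is sensible for datasets dominated
  by one material class; mixed datasets should supply per-group
  references.
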