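---
title: "Grading edible oils from hyperspectral cubes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading edible oils from hyperspectral cubes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Commercial camellia seed oil is sold in quality grades that are usually
assigned by slow wet-chemistry assays and sensory panels. Near-infrared
hyperspectral imaging offers a fast alternative: a line-scan camera
records a reflectance cube (rows x cols x ~250 bands over roughly
870-1720 nm) of oil-filled dishes, and the oil's C-H overtone and
combination bands — absorption features near 960, 1075, 1320, 1510 and
1585 nm — carry grade-related chemistry, while the image plane carries
grade-related color/turbidity texture.

`hsigrade` implements the full modelling pipeline:

1. cube I/O (ENVI header + raw binary), dish segmentation, ROI
   mean-spectrum extraction, replicate averaging;
2. abnormal-sample screening and a Kennard-Stone (K-S)
   calibration/prediction split;
3. per-spectrum preprocessing (Savitzky-Golay smoothing and derivatives,
   min-max normalization, standard normal variate);
4. characteristic-wavelength selection by SPA and CARS over a
   cross-validated PLS core;
5. gray-level co-occurrence matrix (GLCM) texture features at the
   selected wavelengths, optionally from principal-component score
   images;
6. genetic-algorithm-tuned RBF-SVM grading models and paired
   model-family comparisons.

## The grading model

The classifier is a soft-margin support vector machine with RBF kernel
$K(u,v) = \exp(-g\,\lVert u-v\rVert^2)$ and one-vs-one multiclass
handling. Its two hyperparameters — penalty factor $c$ and kernel
parameter $g$ — are tuned by a real-coded genetic algorithm maximizing
stratified $k$-fold cross-validated accuracy on the calibration set
(`ga_svm()`). Accuracy is reported as $100\, m_1/m_2$ percent, the share
of correctly classified samples, rounded half-up to two decimals.

GA defaults: population 20, 50 generations, crossover probability 0.8,
per-gene Gaussian mutation probability 0.1, tournament selection of size
2, elitism 1, with $c$ and $g$ searched on a log10 scale in
$[10^{-2}, 10^2]$. Elitism makes the best-fitness trace non-decreasing,
which the tests assert. Features are min-max scaled to $[0,1]$ with
ranges learned on calibration rows only; prediction rows may fall
outside and are deliberately not clipped (no information about the
prediction set leaks into the scaler).

Two conventions for "model A improved on model B by x%" coexist in the
applied literature: the absolute gain in percentage points and the
relative gain as a share of the baseline. `absolute_improvement()` and
`relative_improvement()` implement both, and `run_matrix()` reports both,
labeled, so the reader never has to guess.

## Wavelength selection

Both selectors operate on calibration rows only and encode the grade
labels as a one-hot (3-column) response for their internal PLS
regression; a band's importance is the Euclidean norm of its coefficient
row, which makes the selection invariant to relabelling the grades (a
tested property).

**SPA** builds, from every candidate start band, a chain of minimally
collinear bands: each addition is the band with the largest residual
norm after orthogonal projection on the span of the chain so far.
Duplicated (collinear) bands have zero residual and can never be
co-selected. The final (start, size) pair minimizes the RMSE of a
least-squares model on an internal 70/30 validation split of the
calibration rows; sizes 5-30 are searched by default.

**CARS** runs `n_runs = 50` elimination rounds. Round $i$ fits PLS on a
random 80% of the calibration rows using the currently retained bands,
computes normalized coefficient weights, keeps the top bands under an
exponentially decreasing schedule (100% of bands at round 1 down to 2
bands at the last round; the two-point exponential is fixed by these
endpoints), and thins further by adaptive reweighted sampling (bands
drawn with probability proportional to weight). Each survivor set's
RMSECV is recorded — with the *same* fold assignment for every round, so
subsets compete on identical folds; re-randomizing folds per round made
the minimum-RMSECV pick unstable at small sample sizes. The full-band
model is recorded as round 0, so the returned subset can never be worse
than no selection under the selection criterion.

The PLS core is a compact NIPALS PLS2 (`pls_fit()`); at full rank with
all components it reproduces ordinary least squares, which the tests use
as a closed-form oracle.

## Texture features

The GLCM of a quantized image counts ordered gray-level pairs $(i,j)$ at
displacement $d$ along directions 0, 45, 90 and 135 degrees, normalized
to a probability matrix $h$. Four statistics are extracted per
direction — contrast $\sum (i-j)^2 h$, energy $\sum h^2$, entropy
$-\sum h \log_{10} h$, and correlation
$(\sum ij\,h - \mu_x\mu_y)/(\sigma_x\sigma_y)$ — giving a 16-element
texture vector (direction-major order). Numerical conventions:

- counting is asymmetric (ordered pairs); a symmetric mode is available;
- gray levels are indexed 0..L-1; quantization is linear binning of the
  in-mask intensity range, 64 levels and $d = 1$ by default;
- the entropy logarithm is base 10 (base 2 and natural available);
- correlation is defined as 0 when a marginal is degenerate (constant
  image), so the statistic is total;
- texture is computed only over the segmented/ground-truth dish mask.

For fusion, the spectral values at the CARS wavelengths are concatenated
with the texture vector (spectral block first). The texture source is
either the mean of the selected band images (`raw_bands`) or a single
principal-component score image of the per-sample selected-band stack
(`PC1`/`PC2`/`PC3`, pixels as observations). The per-PC variants mirror
the common practice of extracting texture from one score image at a
time; a cumulative variant was considered and rejected to keep the
model families directly comparable.

## Sample screening and splitting

Abnormal scans are screened per grade: spectra are SNV-standardized,
each sample's Euclidean distance to the grade's mean standardized
spectrum is computed, and samples beyond
`median + threshold_sd * max(1.4826 MAD, 0.1 median)` are removed
(default `threshold_sd = 2.5`). Two deliberate choices here:

- **robust center/scale** (median/MAD rather than mean/sd): a cluster of
  genuine outliers inflates the mean and sd of the distances enough to
  mask itself entirely — with 8 faulty scans among 56 the classical rule
  flags nothing, at any outlier magnitude, because the cutoff scales
  with the contamination. The classical rule remains available as
  `method = "classic"`.
- **a scale floor** at 10% of the median distance: robust z-scores are
  scale-free, so in a grade whose spectra agree to measurement
  resolution the largest of ~50 cosmetic fluctuations would regularly
  exceed any fixed z cutoff. Flooring the scale makes "everything within
  ~25% of the typical distance" unflaggable, which matches the intent of
  screening for gross acquisition faults.

The K-S split assigns the most spread-out samples to the calibration
set: the first two picks are the globally farthest pair and each later
pick maximizes its minimum distance to the picked set, until
`round(n * 3/5)` samples are selected (3:2 by default). Distances are
computed on SNV-standardized spectra for consistency with the screening
rule (a raw-spectrum mode exists); ties break toward the lowest row
index, making the split deterministic and permutation-invariant up to
exact ties. The split is computed once per data realization and shared
by every model row, so family comparisons are paired.

## The synthetic-data generator

No public raw dataset of graded oil cubes exists, so the package ships a
generator (`synthetic_config()`, `simulate_dataset()`) whose defaults
encode the study conditions the pipeline is meant for:

- 248 bands over 870-1720 nm; Gaussian absorption dips at 960, 1075,
  1320, 1510 and 1585 nm, 30 nm wide (12 nm for the weak 1510 nm
  feature, so it stays a resolvable local minimum beside the strong
  1585 nm band);
- grade-3 reflectance strictly above grades 1 and 2 at every band
  (baselines 0.42 / 0.46 / 0.60); grades 1 and 2 differ only by a few
  percent in their relative absorption-depth pattern. The grades must
  differ in band *shape*, not only in offset — a pure scaling would be
  erased by SNV, contradicting the regime in which scatter correction
  helps;
- per-sample variation: a multiplicative gain (sd 0.01; removed by SNV)
  and a per-peak depth jitter (sd 0.05; survives SNV and is what makes
  grades 1 and 2 genuinely confusable from spectra alone);
- band-coherent multiplicative texture: a smoothed Gaussian random field
  per scan, with correlation lengths 2/4/8 px and amplitudes
  0.03/0.06/0.10 across grades, so GLCM statistics separate the grades
  in the image plane;
- detector noise sd 0.01 per pixel/band, amplified up to 13x toward the
  spectral edges (e-folding width 8% of the range), emulating the
  sensitivity falloff of InGaAs line cameras. These junk edge bands are
  what gives wavelength selection a real job; a per-scan band "flicker"
  knob exists but defaults to 0 — at any useful level it corrupts the
  PLS coefficient weights that drive CARS faster than it hurts the SVM;
- a circular dish (ground-truth mask returned) on a flat 0.05-reflectance
  background, three replicate scans averaged per sample.

What the generator does *not* emulate: radiative transfer or any real
optical model, acid/peroxide-value chemistry, specular highlights, dish
rims, multi-dish frames (each cube is one dish's crop), or wavelength
miscalibration. Passing tests therefore demonstrate that the pipeline's
logic is correct and that its model-family ordering holds under the
stated statistical structure — not that any particular accuracy will be
attained on real scans.

## Problem sizes used by the test suite

Tests run the full pipeline at reduced scale, chosen so the suite
completes comfortably on one CPU: most image-level tests use 24-60-band
cubes of 36x36 to 44x44 pixels; the repeated-study ordering check runs
50 independent synthetic studies of 60 samples each (20 per grade,
44x44 px, 60 bands, 2 replicate scans) with a 12x8 GA. The
`scripts/acceptance.R` report uses 8 such studies. At these sizes the
three model families (full-wavelength GA-SVM, CARS GA-SVM, fused
CARS+GLCM GA-SVM) show the expected ordering: fusion is the best family
and selection stays within one standard deviation of the full-band
model while using ~10-25% of the bands.

## Known limitations

- The NIPALS PLS core targets the band counts used here (hundreds); for
  tens of thousands of variables a kernelized PLS would be preferable.
- `ga_svm()` re-runs cross-validation for every individual in every
  generation; with large calibration sets the GA dominates runtime.
- Segmentation assumes one bright convex region on a darker background
  (Otsu threshold + largest connected component + hole filling); frames
  with several dishes must be cropped first.
- The ENVI reader supports the float32/little-endian payloads the writer
  emits, which is sufficient for round-tripping this package's artifacts
  but not for arbitrary vendor files.
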