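---
title: "Methods: infrared spectral histopathology of tissue microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrared spectral histopathology of tissue microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

FT-IR imaging of a tissue section yields a hyperspectral cube: at every
pixel an absorbance spectrum over the mid-infrared, here 3850–900 cm⁻¹.
Because the spectrum reflects local biochemistry (protein, nucleic acid,
carbohydrate and lipid content), a classifier trained on annotated pixels
can "digitally stain" an unstained section with tissue-class labels, and a
patient's pathology can be read from how much of a chosen class (Cancer)
their biopsy cores contain. `irhisto` implements this chain for
tissue-microarray (TMA) cohorts — many ~1–1.5 mm needle-biopsy cores per
slide, several cores per patient, patients shared between slides — with six
pancreatic tissue classes: Benign, Cancer, Necrosis, Inflammation, Fiber
and Blood.

No public hyperspectral TMA cohort with per-pixel annotations exists, so
the package ships a first-class synthetic generator that reproduces the
*statistical* structure the analysis depends on. Everything downstream is
exercised and validated against it.

## The spectral axis

The acquisition convention is a descending, evenly spaced wavenumber grid.
For the default parameters — 3850–900 cm⁻¹ range, 8 cm⁻¹ resolution,
zero-filling factor 2 — the grid has exactly 765 points including both
endpoints, the count produced by the reference FPA instrument
configuration. That count is not `range/(resolution/zff) + 1` (which would
give 738.5), so `build_spectral_axis()` carries a small lookup for known
acquisition setups and falls back to
`n = floor((high − low)·zff/resolution) + 1` for anything else. Both
endpoints are always included; spacing is `(high − low)/(n − 1)` ≈ 3.861
cm⁻¹ for the default grid.

## The synthetic cohort generator

`generator_config()` + `generate_cohort()` define the study conditions:

* **Class spectra.** Each class is a sum of Gaussian bands on a linear
  baseline. All six classes share a dominant Amide I band at 1652 cm⁻¹
  (the most intense band of any tissue spectrum) and an Amide II band at
  1545 cm⁻¹; classes differ chiefly in the Amide A/B region
  (3550–3000 cm⁻¹) and the nucleic-acid phosphate region (1300–1000 cm⁻¹),
  plus class-specific markers (lipid ester 1740 for Necrosis, a collagen
  multiplet for Fiber, heme modes for Blood). The band tables are a
  documented invention: no quantitative class-mean spectra are published
  for the tissue they emulate. Their amplitudes were fixed once so that
  the minimum pairwise L2 distance between noiseless curves exceeds
  5·noise_sd·√bands, the margin at which the classes are learnable by
  construction.
* **Core geometry.** Cores are closed disks laid out on a grid. Each core
  is partitioned into contiguous, irregular class regions by a random
  Voronoi tessellation of the disk; region classes are drawn from
  pathology-conditional frequency tables. Cancer-patient cores always
  contain Cancer, Fiber, Necrosis, Inflammation and Blood regions (plus
  sampled extras), benign cores are Benign-dominated, and
  inflammation-patient cores mix Benign and Inflammation. The guarantee
  keeps the rare classes present in every split of a small cohort; it is a
  deliberate simplification of real morphology.
* **Pixel model.** A tissue pixel's spectrum is
  `jitter × class band sum + baseline + paraffin residual + N(0, noise_sd)`.
  The amplitude jitter (CV 0.05) is a *smooth* random surface per core —
  bilinear upsampling of a coarse Gaussian grid — emulating slowly varying
  section thickness; spatially white amplitude jitter would be
  indistinguishable from detector noise to any spatial noise estimator
  and is not how real sections vary. The residual paraffin band
  (1462 cm⁻¹, σ = 10, amplitude 0.05 × Uniform(0.5, 1.5)) is drawn once
  per core: deparaffinization efficiency varies between cores, not
  between neighbouring pixels. Background pixels carry a flat 0.08
  absorbance. Values are floored at zero, which at the default noise
  level is a ~6σ event.
* **Noise.** SD (2.7 µm pixels) uses `noise_sd = 0.008` absorbance,
  typical of FPA FT-IR pixel noise; HD (1.1 µm pixels) multiplies it by 2
  — the HD configuration collects fewer photons per pixel at matched
  time, so HD models are noisier. HD also rescales core radii by
  2.7/1.1 so the physical scene is unchanged.
* **Cohort.** Desk-scale defaults: 3 arrays × 6 cores of radius 24 px,
  15 patients (5 benign, 4 inflammation, 6 cancer), of whom
  `round(0.2 × 15) = 3` appear on two arrays. These sizes keep a full
  pipeline run under a minute while leaving every pathology group
  representable in all three patient sets; larger cohorts are plain
  configuration changes.

What the generator does **not** model: Mie scattering and dispersion-line
distortions, instrument drift, annotation error, and real histological
morphology. Tests passing on this generator therefore demonstrate the
pipeline's correctness and its behaviour under the stated noise model, not
clinical performance on real tissue.

## MNF denoising

Minimum Noise Fraction denoising whitens the data by an estimate of the
noise covariance, eigendecomposes the whitened signal covariance, and
reconstructs each spectrum from the leading *k* components (default
`k = 20`), zeroing the rest. Noise covariance comes from half-differences
of adjacent pixels, `d = (x₁ − x₂)/√2`; horizontal and vertical neighbour
pairs are pooled, which makes the estimate — and hence the output —
symmetric under image transposition. The noise covariance diagonal is
ridged by `1e-8 × trace/bands` (escalating to `1e-4 × max diag` if the
Cholesky still fails) before whitening.

Denoising is applied **core by core**: the transform fitted on one core's
pixels never touches another core's reconstruction, so no statistic can
leak between patients. Cores too small to fit the transform pass through
unchanged with a warning. A caveat worth knowing: with few pixels per band
(cores barely larger than the band count) the sample covariances are noisy
and truncation can *hurt* accuracy against the clean scene; the package's
MSE tests use cores with comfortably more pixels than bands, and the same
consideration applies to real data.

## Metrics

Each spectrum is reduced to "metrics". For every region of a curated table
the segment between the region's endpoints (nearest axis points,
inclusive) is corrected by subtracting the chord through its endpoint
values, then three statistics are taken: trapezoidal **integral** (absolute
spacings, so descending grids give positive areas), **maximum**, and
**center of gravity** `Σνy/Σy`. Each is divided by the corresponding value
of the Amide I reference region (1700–1600 cm⁻¹). The reference region
itself is not emitted, and the default table has 41 emitted regions, hence
123 metrics per spectrum. The published curated region list is not
available; the default table is a reconstruction tiling the standard IR
biomarker windows (Amide A/B, CH stretches, ester carbonyl, Amide II
sub-bands, the 1450–910 fingerprint including DNA/RNA phosphate windows),
deliberately avoiding the paraffin-contaminated window around 1462 cm⁻¹.
Any user table is accepted; 123 is a property of the default, not a
constraint.

Degenerate cases: a center of gravity over a non-positive-mass segment is
recorded as 0 and counted (a masked noise pixel should not abort a run); a
spectrum whose Amide I reference integral, maximum or center of gravity is
non-positive fails quality control and is excluded with a count. The
normalization of the center of gravity by the reference center of gravity
only rescales a wavenumber by a constant, but it is applied anyway so that
all three statistics are treated identically.

## Splits and balanced sampling

Patients are the unit of partitioning. `make_split_plan()` stratifies by
pathology group and assigns every patient to exactly one of model /
validation / test (defaults 0.5 / 0.25 / 0.25 — the source cohort's exact
fractions are not published), guaranteeing each group at least one patient
per set; a patient whose cores sit on several arrays still gets a single
assignment. Model-set patients are dealt into 4 cross-validation folds,
balanced to within one patient and stratified by group as far as the
counts allow (a strict "four patients per group per fold" requirement
would be unsatisfiable at desk scale).

`balanced_sample()` makes the training draw doubly balanced: every class
contributes the same pixel count, set by the scarcest class; within a
class, the count is split evenly across arrays, arrays short of their
share contribute everything and the deficit is topped up one pixel at a
time round-robin (ascending array id) over arrays with spare pixels.
Sampling within a cell is uniform without replacement.

## Classification and digital staining

A 50-tree random forest (the `randomForest` implementation; other
hyperparameters at library defaults, recorded in the run manifest) is
trained on the balanced draw, deterministic under its seed.
`predict_image()` paints each masked pixel with its argmax-posterior class
— plain argmax, no posterior threshold — and keeps the full posterior
stack. The rendering palette is fixed, with Benign green by convention.

## Evaluation

* **Pixel level**: one-vs-rest ROC per class on the class posterior over
  test-set annotated pixels. The ROC sweeps distinct score values; tied
  scores move the operating point diagonally, so trapezoidal integration
  equals the Mann–Whitney statistic under the midrank convention (tested
  to 1e-12 against exhaustive pair enumeration and against pROC).
* **Core / patient level**: an entity's score is the content of the chosen
  class(es) among its predicted tissue pixels. The default is the
  *fraction* (chosen-class pixels / tissue pixels), robust to patients
  contributing different numbers of cores; a raw *count* mode is also
  available since either reading is defensible. Patient scores pool all
  the patient's cores. Supported contrasts: cancer vs rest, and
  inflammation vs benign (cancer entities excluded).
* **Operating point**: sensitivity and specificity are reported at the
  Youden-J point (max TPR − FPR) of the patient ROC — a standard choice
  where no operating-point rule is prescribed.

Entities with no tissue pixels are excluded with a log entry; an AUC over
a single class of ground truth is an error, not a number.

## Numerical and design choices

* All randomness flows through explicit seeds; stage seeds derive from the
  master seed by a fixed counter scheme (`seed × 1000 + stage`, reduced
  mod 2³¹ − 1). Reruns are bit-reproducible, and artifact hashes in the
  run manifest make that checkable.
* Cube I/O is ENVI header + binary with 64-bit doubles, so round-trips are
  exact; labels are 8-bit PNG with a JSON class-table sidecar; manifests
  and split plans are JSON.
* The tissue mask thresholds the band nearest 1650 cm⁻¹ (Amide I); the
  default threshold is Otsu's on that band image — parameter-free, and
  exact on the generator where background and tissue are well separated —
  with a fixed override for reproducibility against real data.
* Eigen ties in MNF keep the eigen routine's stable ordering; region
  endpoints map to nearest axis points, both inclusive; a region narrower
  than one axis spacing is rejected rather than silently collapsed.

## Problem sizes used by the shipped checks

The reference ("desk-scale") run used by the acceptance script and the
surrogate performance tests is the default configuration above: ~32,600
tissue pixels over 18 cores, ~9,000 annotated test pixels, 4–5 test
patients, 765 bands, MNF k = 20, 123 metrics, 50 trees. The module tests
use smaller scenes (2 arrays, radius 10 cores, a 185-point axis) chosen so
each property is tested in a statistically well-posed regime.

## Known limitations

* Patient-level ROC on a desk-scale cohort rests on very few test
  patients; it verifies the aggregation machinery, not a clinical effect
  size.
* The default region table and class band tables are synthetic
  reconstructions; real-data use should supply the laboratory's own
  region list via `region_table()`.
* MNF assumes spatially uncorrelated noise and locally smooth signal;
  structured noise (fringing, drift) violates that and is not modelled.
* The generator's classes are honest about their own separability: with
  the default noise they are designed to be learnable, so high AUCs on
  synthetic runs certify the pipeline, not the difficulty of pancreatic
  histopathology.
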