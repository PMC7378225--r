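---
title: "Grey-level texture analysis of the post-EVAR aneurysm sac: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-level texture analysis of the post-EVAR aneurysm sac: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sactexture)
```

## The problem

After endovascular aneurysm repair (EVAR) of an abdominal aortic aneurysm
(AAA), the excluded aneurysm sac should thrombose and shrink. A sac that
instead expands signals persistent pressurisation — often an endoleak — and
may require re-intervention. Expansion is conventionally detected only at a
later follow-up CT, by comparing sac volumes. The hypothesis behind this
package is that the *texture* of the thrombosed sac on the **first**
post-operative contrast CT already carries the signature of later expansion:
a sac perfused by residual flow shows spatially heterogeneous contrast
pockets, while a sealed sac thromboses homogeneously.

`sactexture` implements that analysis end to end: masked grey-level texture
features of the sac region of interest (ROI), a volume-change reference
standard for the expansion label, a three-layer backpropagation neural
network classifier evaluated under repeated stratified splits, and the
conventional comparison arms (univariable screening plus binary logistic
regression on clinical and imaging covariates). Because patient CTs cannot
be redistributed, the package ships a synthetic phantom generator that
reproduces the statistical structure the analysis assumes, and the whole
pipeline is exercised and tested on phantoms.

## Texture model

All three feature families operate on a quantized ROI: the in-mask
intensities are rebinned into `G` equal-width levels between the in-mask
minimum and maximum (default `G = 16`, the conventional level count for
noise suppression in CT texture work). Min–max binning per ROI makes every
feature invariant to affine intensity rescaling, i.e. to scanner offset and
gain; the alternative — binning over a fixed HU window — would tie features
to absolute calibration, which a single-centre convention cannot guarantee.
Levels are 1-based (`1..G`) so the run-emphasis features that divide by the
squared grey level are always well defined. Analysis is 2D, on the single
largest axial cross-section of the sac, with the ROI being the annulus
between the stent lumen and the outer sac contour.

Three matrices are computed, each over the four principal directions
(0°, 45°, 90°, 135°) under an isotropy assumption, with each feature
averaged across directions:

* **GLCM** — the grey-level co-occurrence matrix `P(i, j)`: the symmetric
  joint distribution of level pairs at displacement `d` (default 1 pixel).
  Thirteen classic Haralick features are derived: energy (angular second
  moment), contrast (inertia), correlation, entropy, inverse difference
  moment, sum average/variance/entropy, difference
  average/variance/entropy, and the two information measures of
  correlation. Logarithms are base 2 with `0·log 0 = 0`; the correlation of
  a zero-variance marginal is defined as 0; the second information
  measure's radicand is clipped at 0.
* **GLRLM** — the run-length matrix `R(i, j)`: counts of maximal
  equal-level runs of length `j` at level `i`. Masked-out pixels break
  runs (a run never jumps a gap), so runs tile the in-mask pixels exactly:
  `Σ j·R(i,j) = Np` per direction — an identity the tests assert. The seven
  Galloway/Chu features are SRE, LRE, GLN, RLN, RP, LGLRE and HGLRE.
* **GLDM** — the histogram of absolute level differences at a fixed
  displacement. Five features: contrast, angular second moment, entropy,
  mean, and inverse difference moment with the `k² + 1` denominator so the
  zero-difference bin contributes.

Direction averaging is done at the **feature** level (13/7/5 features per
direction, then the mean), the standard isotropic-Haralick convention;
averaging the matrices first is available via
`glcm_features(average = "matrices")` for sensitivity analysis. On a
constant ROI both conventions coincide.

## Reference standard and cohort filtering

The expansion label derives from two follow-up volumes: a patient is
`expansion` iff `(V2 − V1)/V1 > 2%`, **strictly** — a change of exactly 2%
is non-expansion. The relative change is computed on the stored volumes
with no rounding, and the label is invariant to rescaling both volumes by
a positive constant. When a delineated 3D mask is available,
`volume_from_mask()` supplies voxel-counting volumes (voxels × voxel
volume).

Type-I (attachment-site) endoleaks are a strong independent mechanical
driver of expansion; `exclude_type1()` removes them before texture
modelling so the texture signal is not confounded, and reports the
per-group bookkeeping. The filter is idempotent and removes all type-I
records.

## Classifier and evaluation design

The classifier is a three-layer backpropagation network (`mlp_net()`):
logistic activations throughout, a single probabilistic output, binary
cross-entropy loss, trained full-batch with Adam (learning rate 0.05, at
most 500 epochs). "Three-layer" is read as input–hidden–output with one
hidden layer of width 10 by default; `hidden = c(h1, h2)` gives the
two-hidden-layer reading for anyone wanting the alternative
interpretation. Features are z-scored with training-set statistics inside
the fit — validation and test data never touch the standardization, which
the test suite asserts with a label-copy canary feature.

Evaluation follows the repeated-split design: `n` repeats (default 100) of
a stratified random 70:15:15 train/validation/test partition. Partition
sizes use largest-remainder rounding applied per class (92 patients split
as 64/14/14; each partition's class fraction is within one patient of the
cohort's). The 15% validation partition exists for early stopping: training
keeps the weights with the lowest validation loss and stops after 20
non-improving epochs. The test partition is scored once; per-repeat AUC and
Youden-cutoff confusion metrics are averaged across repeats ("mean of
repeats" is the headline aggregate; a pooled-score ROC over all repeats is
also reported). No class reweighting is applied at the ≈32:60 imbalance of
the filtered cohort.

ROC curves are empirical: a case is called positive when its score strictly
exceeds the threshold; internal thresholds are midpoints between distinct
scores; AUC is the trapezoid integral, equal to the tie-corrected
Mann–Whitney statistic. The operating point maximises Youden's J with ties
broken toward higher specificity, and the reported cutoff is the midpoint
of the optimal threshold interval. All-tied scores give AUC 0.5 by
convention.

The comparison arms mirror conventional practice: continuous variables are
screened by Lilliefors-corrected Kolmogorov–Smirnov normality (a failure
logs a warning only, since the group comparison proceeds by t test
regardless — Welch by default, pooled behind a flag) and two-sample t
tests; categorical variables by chi-square, switching to Fisher's exact
test when any expected cell is below 5. Variables pass at P < 0.1 or by
clinical-importance forcing (default: endoleak and maximal diameter).
`fit_logistic()` fits the binary logistic model by IRLS with "no endoleak"
as the dummy reference level, flags (quasi-)separation explicitly, and its
predicted probabilities feed the same ROC machinery
(`model_probability_roc()`).

## The phantom generator

`render_sac_image()` draws a square scene: background, a bright circular
stent lumen (fixed scene intensity 300), and a thrombus annulus at
`thrombus_mean` (default 60) with Gaussian pixel noise (`thrombus_sd`,
default 12) optionally blurred into spatially correlated texture
(`smoothing_sigma_px`, default 1.5 px). For an expansion-prone sac,
`n_pockets` (default 5) isotropic Gaussian contrast pockets
(`pocket_amplitude`, default 150; `pocket_sigma_px`, default 4 px) are
added at uniformly random in-mask centres — the image model of residual
perfusion: uneven contrast distribution and poor CT-value uniformity.
Intensities are HU-like arbitrary units clipped to the 16-bit container
range; images are written as 16-bit single-channel TIFF and masks as 8-bit
PNG. The pocket count is fixed per image (not Poisson) so fixtures are
bit-reproducible from seeds; zero `pocket_amplitude` makes the two groups
exchangeable, the null configuration the tests exploit.

`generate_cohort()` adds the tabular layer. First-interval volumes are
log-normal with moments matched to 156.9 ± 133.6 cc — log-normal rather
than normal because the SD is of the order of the mean and volumes must be
positive. Relative changes are normal per group: 9.8% ± 9.9% (expanders)
and −8.7% ± 10.7% (non-expanders). Endoleak types are drawn per group at
the observed group rates (6/6/26 of 38; 1/6/54 of 61). Clinical covariates
(age, sex, pressures, lipids, smoking, alcohol, diameter) are drawn from
distributions matching the published cohort summaries but **independently
of group** — no clinical variable discriminated the groups in the source
cohort, so on phantoms the clinical arms' expected AUC is 0.5 by
construction, which turns the comparison design itself into a testable
contract.

### What the phantoms do and do not show

The phantoms carry the statistical structure the pipeline assumes —
group-dependent texture heterogeneity, realistic volume distributions,
label-independent covariates — and none of the physics of real CT: no beam
hardening, stent metal artefacts, partial-volume effects, 3D geometry, or
anatomic variation. A passing benchmark on phantoms demonstrates that the
pipeline recovers a known texture signal and does not hallucinate one from
noise; it says nothing about effect sizes in real patients.

One consequence of using the published change distributions deserves
emphasis. Because the expander distribution (9.8% ± 9.9%) has substantial
mass below the 2% threshold and the non-expander distribution
(−8.7% ± 10.7%) has mass above it, the volume-derived label disagrees with
the generating group for roughly 21% of expanders and 16% of
non-expanders. That is a property of the study conditions, not a bug: real
volume measurements are similarly noisy relative to a 2% margin. For the
discrimination benchmark we therefore score the classifier against the
generating group (the phantom's ground truth); scoring against the
volume-derived label would mix irreducible label noise into the texture
benchmark and cap the attainable AUC near 0.81 regardless of feature
quality. Both columns (`group` and `label`) travel with the manifest so
either analysis is a one-liner.

## Numerical choices and degenerate inputs

* Quantization refuses an empty mask and `G < 2`; ROIs smaller than `G`
  pixels are accepted with a warning (a single-pixel ROI quantizes to
  level 1).
* A co-occurrence/difference matrix with no valid pixel pair at the
  requested displacement raises an error distinct from the empty-mask
  error.
* Constant feature columns get unit scale in standardization and
  contribute nothing to the network; a fully constant feature table yields
  a constant score and AUC 0.5.
* Per-patient image seeds are derived as `pparams$seed + patient index`,
  keeping every seed a valid 32-bit integer; the full cohort is
  bit-reproducible from `(cohort seed, phantom seed)`.
* Benchmarks in the test suite run the full published-scale design — a
  99-patient cohort (38 expansion-prone), 100 evaluation repeats — and a
  2000-expander calibration cohort; both complete in seconds because the
  network is tiny and feature extraction is vectorised.

## Known limitations

* 2D single-slice analysis only; no 3D texture matrices or multi-distance
  aggregation (`d` is configurable but defaults to 1, as the classic
  feature sets assume).
* The GLDM feature list follows the classical five-feature set (contrast,
  ASM, entropy, mean, inverse difference moment); a "correlation"-flavoured
  variant sometimes named in its place is not implemented.
* Screening applies no multiple-testing correction, matching the
  conventional univariable-screening practice it reproduces.
* Logistic odds ratios under quasi-separation are reported with a warning
  but not penalised (no Firth correction).
* The phantom's endoleak appearance is a free modelling choice (Gaussian
  pockets); no quantitative imaging description of endoleak texture was
  available to calibrate against, so pocket parameters are exposed rather
  than fixed.

## Worked example

```{r example, eval = FALSE}
cohort_dir <- tempfile("phantoms")
manifest <- generate_cohort(cohort_params(seed = 101),
                            phantom_params(seed = 11), cohort_dir)

features <- extract_cohort_features(manifest)
glcm_cols <- grep("^glcm_", names(features), value = TRUE)

labeled <- apply_reference_standard(manifest)
kept <- exclude_type1(labeled)$cohort

ev <- evaluate_feature_set(features[glcm_cols], manifest$group,
                           n_repeats = 100, seed = 5)
ev
```
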