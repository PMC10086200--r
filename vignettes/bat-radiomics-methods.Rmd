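---
title: "Detecting brown adipose tissue on nonenhanced CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brown adipose tissue on nonenhanced CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Brown adipose tissue (BAT) is thermogenic fat: small lipid droplets, dense
mitochondria, and — when activated — avid glucose uptake. The reference
standard for detecting it in humans is ^18^F-FDG PET-CT under the BARCIST 1.0
criteria: a depot voxel counts as adipose when its CT attenuation lies in the
closed window [−190, −10] HU, and as BAT when, in addition, its standardized
uptake value (SUV) is at least 1.5. PET, however, requires tracer injection
and misses unactivated BAT. Because BAT's microstructure also changes its CT
appearance — it is slightly denser and more heterogeneous than white adipose
tissue (WAT) — a texture ("radiomics") model fitted on nonenhanced CT alone
can plausibly recognize BAT without PET. `batscan` implements that entire
analysis as a tested pipeline: phantom simulation, BARCIST reference
labeling, large-scale feature extraction, reproducibility- and
redundancy-based feature selection, an SVM radiomics score with a
Youden-index cutoff, symmetry-aware per-patient diagnosis, and Agatston
scoring of coronary (CAC) and thoracic-aorta (TAC) calcium for the
cardiovascular-protection comparison.

## The phantom: what it emulates, and what it does not

No patient images ship with the package; a seeded phantom generator
(`phantom_spec()`, `generate_cohort()`) produces paired CT/PET volumes whose
*statistical* structure matches what the analysis assumes:

* **Geometry.** Each patient carries 6–13 depots: bilateral cervical,
  supraclavicular and axillary pairs (up to two pairs per region) plus up to
  three midline mediastinal depots, placed as jittered ellipsoids on a
  20 × 72 × 72 lattice at 5 × 1 × 1 mm spacing (5 mm slices, as in routine
  chest CT). Depots and the CAC/TAC territories are kept disjoint by an
  occupancy mask.
* **Class contrast.** WAT depots have mean −100 HU with a Gaussian random
  field texture (SD 8 HU, correlation length ≈ 0.45/1.1 voxels
  through-plane/in-plane). BAT depots are shifted by +10 HU, rougher
  (SD 11 HU) and shorter-range (0.35/0.8). Each depot's mean is additionally
  jittered by a N(0, 18 HU) biological-heterogeneity term; without it the
  classes separate perfectly, which no real cohort does. These effect sizes
  are free parameters of the phantom — the literature gives no quantitative
  BAT/WAT CT texture contrast — and were fixed once so that the depot-level
  discrimination of the fitted model lands in the high-0.8/low-0.9 AUROC
  range reported for real cohorts, then left alone.
* **PET truth.** BAT depots draw SUV from U(2, 6) clipped to ≥ 1.5; WAT from
  U(0.3, 1.2) clipped below 1.45. Depot HU is clipped to [−190, −10], so the
  BARCIST labels recover the generating truth exactly — a deliberate
  round-trip property used by the tests.
* **Symmetry.** Within a BAT-positive patient, BAT status is assigned to
  bilateral *pairs* as a unit with probability 0.55 (10% of pairs activate
  one side only) and to mediastinal depots individually. This is the
  physiologic symmetric distribution that the per-patient criterion 2
  exploits.
* **Calcium.** Patients receive calcified lesions in each territory with
  probability 0.05 (BAT) versus 0.25 (non-BAT) — the protective-association
  direction and rough magnitude seen clinically; lesions are 4–20 voxels at
  150–800 HU, grown inside the territory with a 1-voxel halo so they remain
  distinct connected components.
* **Sites.** `site_hu_shift` adds a global HU offset to emulate a second
  scanner for external validation.

The phantom does **not** emulate anatomy (no body outline, organs, or air),
scanner noise spectra, PET kinetics, partial-volume effects, or DICOM
acquisition. Tests passing on the phantom therefore demonstrate that the
*pipeline machinery* is correct and that signal of the assumed kind is
recovered; they cannot certify performance on real patients.

A single integer seed drives a hierarchical per-patient stream
(`sample.int` of per-patient seeds), so cohorts are reproducible
voxel-for-voxel and extensible without rewriting earlier patients.

## Preprocessing

Volumes are resampled in-plane to 1 × 1 mm by an order-1 B-spline
(trilinear); a zero in `target_spacing` means "keep the input spacing", and
the through-plane axis is kept by default. Masks are resampled
nearest-neighbour and re-binarized. The conventional soft-tissue display
window ([40, 400] HU) is provided as `apply_window()` but is *not* applied
before feature extraction: it would clip the entire adipose range to a
constant. Features are computed on raw HU.

Gray levels are discretized with a fixed bin width (default 25 HU) anchored
at the ROI minimum: `level(v) = floor((v − min)/w) + 1`. Fixed-width binning
is robust to ROI-dependent ranges and makes all texture features invariant
to a constant intensity shift — a property the tests assert.

### The filter bank (19 image types)

Radiomics features are computed on the original image and 18 filtered
versions: the 8 sub-bands of a single-level stationary (undecimated) Haar
wavelet transform (LLL … HHH), Laplacian-of-Gaussian at σ ∈ {1, …, 5} mm
(scale-normalized by σ²), and five intensity transforms. The transforms are
magnitude-normalized so filtered images stay on a scale commensurate with
the input (`M = max |x|`, `R = range`):

| filter | formula |
|---|---|
| square | `x² / M` |
| square root | `sign(x) · sqrt(M · |x|)` |
| logarithm | `sign(x) · log(1+|x|) · M / log(1+M)` |
| exponential | `exp((x − min x) · log(1+R) / R)` |
| gradient | central-difference gradient magnitude (per mm) |

The exponential transform is anchored at the ROI minimum rather than at
zero; an origin-anchored exponential maps the whole (negative) fat range
into (0, 1) and would collapse to a single 25-HU bin, making every
exponential-type texture feature degenerate by construction.

With 19 image types and the feature classes below, the census per depot is
19 × (18 + 22 + 16 + 16 + 14 + 5) + 14 = **1,743 features** — 342
first-order, 14 shape, and 1,387 texture (418 GLCM, 304 GLRLM, 304 GLSZM,
266 GLDM, 95 NGTDM).

## Feature definitions and numerical conventions

Texture matrices are accumulated in compiled code (`src/kernels.cpp`); the
formulas are evaluated in R. Conventions that matter:

* **GLCM**: distance 1, the 13 unique 3D directions, symmetrized and
  normalized per direction, features averaged over directions. A
  single-level ROI defines correlation = 1 and the information measures = 0;
  inverse variance sums off-diagonal entries only. Directions with no valid
  voxel pairs are skipped from the average.
* **GLRLM**: runs per the same 13 directions, features averaged.
* **GLSZM**: zones are 26-connected components of equal level.
* **GLDM**: dependence of a voxel = number of 26-neighbours inside the ROI
  with identical level (tolerance α = 0); matrix indexed level ×
  (dependence + 1).
* **NGTDM**: 26-neighbour mean differences; ratios with empty denominators
  are 0 and coarseness of a flat ROI is capped at 10⁶.
* **First order** uses the population variance convention; skewness and
  kurtosis of a constant ROI are defined as 0; entropy/uniformity use the
  same fixed-bin-width histogram as the texture matrices.
* **Shape** (computed once, on the original image): surface area and mesh
  volume come from a marching-tetrahedra iso-0.5 surface of the mask
  indicator lightly smoothed with a Gaussian (σ = 0.7 voxel) — the smoothing
  regularizes the voxel staircase so the sphericity of digital balls
  approaches 1 with radius, and the mesh volume follows from the divergence
  theorem over the consistently oriented closed surface. Masks too small to
  clear the iso level fall back to the raw indicator. Axis lengths are
  4·√λ of the voxel-coordinate covariance eigenvalues; a single-voxel mask
  reports elongation = flatness = 1. Maximum 2D diameters use
  boundary-voxel centers per orthogonal plane.

Degenerate inputs never produce NaN/Inf: every feature has a documented
fallback, because small phantom depots and aggressive filters do produce
single-bin ROIs in practice.

## Reference labeling

`label_depot()` applies BARCIST exactly as printed: adipose = HU in the
closed interval [−190, −10]; BAT = adipose and SUV ≥ 1.5 (boundary values
count); a depot is BAT when it has at least `min_bat_voxels` (default 1 —
no minimum is specified clinically, so the strict reading is the default) and
a patient is BAT-positive when any depot is. An ROI without adipose voxels
is labeled non-BAT and flagged with a warning record rather than an error.

## Feature selection

The cascade has three stages, each recorded with a removal reason:

1. **ICC filter.** A second segmentation is simulated by an in-plane
   morphological perturbation of each mask (random 1-pixel 4-connected
   dilation or erosion plus 20% boundary-pixel jitter — in-plane because
   manual segmentation proceeds slice by slice). Per feature, ICC(2,1)
   (two-way random effects, absolute agreement, single measures — the
   conventional inter-observer form) is computed across depots between the
   two extractions; features with ICC < 0.80 are removed. The ICC stage is
   label-free and uses all development depots.
2. **Pearson redundancy pruning.** Among pairs with |r| > 0.90 (scanned by
   descending |r|, ties broken lexicographically), the member with the lower
   point-biserial correlation against the 0/1 BAT label is removed.
   Constant columns have correlation 0 by definition. Supervised stages use
   the training depots only.
3. **LASSO.** L1-penalized *linear* regression on the binary label (the
   linear-model variant is the default deliberately; a logistic variant
   would be a one-line change), over standardized features, with the penalty
   chosen by seeded cross-validated AUROC along the glmnet path; nonzero
   coefficients form the final set. An empty selection at every penalty is
   an error advising a weaker grid.

## Scoring and diagnosis

The depot classifier is an RBF-kernel SVM (`e1071`) with
inverse-median-distance bandwidth, inverse-class-frequency weights (the
cohort has roughly 1 BAT : 1.8 non-BAT depots), and Platt-style probability
calibration fitted by internal cross-validation; the calibrated probability
is the radiomics score RS ∈ [0, 1]. The cutoff RS\* maximizes the Youden
index J = sensitivity + specificity − 1 over the observed training scores,
evaluating candidates with the rule "positive iff score ≥ t" and resolving
ties toward the **higher** threshold (favouring specificity); depots are
then called positive iff RS > RS\* (strictly). With continuous SVM scores
the ≥/| > boundary distinction has probability zero; both conventions are
kept because each is the literal reading of its respective rule. Degenerate
cutoffs (J ≤ 0: inverted or constant scores) are flagged rather than hidden.

Per patient, two criteria are applied to the depot calls: criterion 1 —
any positive depot; criterion 2 — a bilateral region (cervical,
supraclavicular, axillary) positive on *both* sides, or any positive
mediastinal depot. "Symmetric pair" is operationalized by region label and
opposite laterality within the patient; no spatial-coordinate check is
performed. Criterion 2 positivity implies criterion 1 positivity, so over
any cohort sensitivity(c2) ≤ sensitivity(c1) and specificity(c2) ≥
specificity(c1) — a containment the tests verify exhaustively over all 2⁶
positivity patterns of a six-depot patient.

Depots are split 7:3 into training and internal validation at the *depot*
level, stratified by label and seeded. A depot-level split leaks patient
identity across splits; that is the study design being reproduced, and a
patient-level split is available by grouping on `patient_id` before calling
`split_cohorts()`. Patient-level diagnostics use all development patients
(the development cohort is not split at patient level).

## Calcium scoring

Lesions are per-slice 8-connected components of voxels with HU **strictly**
greater than 130 inside a territory mask, discarding components under 3
pixels ("at least three adjacent pixels"). The printed strict ">" is kept
even though the conventional Agatston threshold is ≥ 130. Per lesion-slice,
the density weight is 1–4 by maximum HU band (130–199/200–299/300–399/≥400)
and the slice score is in-plane area (mm²) × weight; scores sum over
components, and calcium volume is voxel count × voxel volume. Scores are
computed at the input spacing, which is recorded in the result; the classic
3 mm-slice Agatston assumption is noted, and no slice-thickness rescaling is
applied. Group comparisons report incidence over all patients and
mean ± SD over calcium-positive patients only (all patients still enter the
significance test).

## Evaluation machinery

Proportion metrics carry exact Clopper-Pearson 95% intervals; AUROC is the
midrank Mann-Whitney statistic with a DeLong placement variance (the CI
method is a documented choice — nothing in the design fixes DeLong over
bootstrap). "AUROC-cutoff" is the rank AUROC of the binarized calls, which
equals (sensitivity + specificity)/2 — the only reading consistent with a
one-number-per-criterion summary. Propensity matching fits a logistic model,
then greedily pairs cases (seeded random visiting order) to the nearest
unmatched control within a caliper of 0.1 on the propensity scale, without
replacement. Group comparisons route continuous data through a
Kolmogorov-Smirnov normality screen (groups under 8 observations go straight
to the rank test) to Student's t or Mann-Whitney, and categorical data to
chi-squared or Fisher's exact test by the all-expected-counts ≥ 5 rule.

## Problem sizes

The packaged study analogue uses 86 development patients (≈ 800 depots,
each extracted twice for the two raters) and a 40-patient external cohort —
the sample sizes of the original design — which the test suite and the
acceptance script regenerate from scratch in a few minutes on one core.
Oracle sweeps (texture matrices vs. brute-force enumeration, Agatston vs.
hand scoring, Youden/AUROC vs. exhaustive pair counting) run on exhaustive
small-shape grids with seeded random level assignments.

## Known limitations

* Phantom effect sizes are assumptions, not estimates of BAT biology; all
  recovered AUROCs quantify the pipeline under those assumptions.
* The 19-type filter bank is the standard census-consistent reconstruction;
  other banks of the same size exist.
* SVM probability calibration depends on e1071's internal fold RNG; models
  are reproducible only through the recorded seed.
* The second "rater" is a morphological perturbation, not a human; ICC
  pass rates transfer to real inter-observer data only qualitatively.
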