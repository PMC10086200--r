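# batscan

Radiomics detection of brown adipose tissue (BAT) on nonenhanced chest CT.

Active BAT is normally confirmed by ^18^F-FDG PET-CT under the BARCIST 1.0
rule — a depot voxel is adipose when its attenuation lies in [−190, −10] HU
and BAT when its SUV is ≥ 1.5 — but PET needs tracer, and quiescent BAT
escapes it entirely. Because BAT's microstructure (small lipid droplets,
dense mitochondria) also alters its CT appearance, its presence can be
modeled from CT texture alone. `batscan` implements that analysis
end-to-end as a tested R package:

* **Phantom cohorts** (`phantom_spec()`, `generate_cohort()`): seeded paired
  CT/PET volumes with bilaterally symmetric cervical / supraclavicular /
  axillary and midline mediastinal depot masks (6–13 per patient),
  coronary/aortic territory masks with injectable calcified lesions, and
  ground-truth tables. NIfTI/CSV export via `write_cohort()`.
* **Reference labeling** (`label_depot()`, `label_cohort()`): the BARCIST
  joint HU-window + SUV-threshold rule, with exact closed bounds.
* **Radiomics extraction** (`extract_features()`): 1,743 features per depot
  — 18 first-order and the GLCM/GLRLM/GLSZM/GLDM/NGTDM texture families
  over 19 image types (original, 8 stationary-Haar wavelet bands,
  Laplacian-of-Gaussian σ = 1–5 mm, square, square root, logarithm,
  exponential, gradient) plus 14 mesh-based 3D shape descriptors. Texture
  matrices are accumulated in compiled code.
* **Feature selection** (`select_features()`): ICC(2,1) reproducibility
  filter against a perturbed second segmentation (< 0.80 excluded), greedy
  Pearson redundancy pruning (|r| > 0.90, weaker label correlation
  removed), then LASSO with the penalty chosen by cross-validated AUROC.
* **Scoring and diagnosis** (`train_depot_model()`, `classify_depots()`,
  `call_patients()`): RBF-SVM radiomics score (RS) calibrated to [0, 1],
  Youden-index cutoff RS\*, strict RS > RS\* depot positivity, and two
  patient rules — any positive depot (criterion 1) or a symmetric positive
  pair / positive mediastinal depot (criterion 2).
* **Calcium** (`detect_lesions()`, `agatston_score()`): Agatston scoring of
  coronary (CAC) and thoracic-aorta (TAC) calcium — per-slice 8-connected
  components of > 130 HU with ≥ 3 pixels, area × density-weight scoring —
  and BAT-RS vs non-BAT-RS group comparison.
* **Evaluation** (`diagnostics()`, `propensity_match()`,
  `group_compare()`): sensitivity/specificity/PPV/NPV/accuracy with
  Clopper-Pearson intervals, rank AUROC with DeLong intervals, 1:1
  caliper-0.1 propensity matching, and routed two-group tests.

`run_pipeline()` chains every stage — simulate → label → extract (two
raters) → select → train → diagnose → calcium → evaluate — from a single
seeded `run_config()`.

## Worked example

```r
library(batscan)

cfg <- run_config(phantom = phantom_spec(n_patients = 86, rng_seed = 20260927),
                  seed = 1)
run <- run_pipeline(cfg, progress = TRUE)

run$selection$counts
#>     census   post_icc post_prune      final
#>       1743        218         90         34

round(run$model$cutoff, 3)
#> [1] 0.375

g <- function(d, m) d$estimate[d$metric == m]
round(c(train    = g(run$depot_diagnostics$train, "auroc"),
        internal = g(run$depot_diagnostics$internal, "auroc")), 3)
#>    train internal
#>    0.984    0.923

round(rbind(criterion1 = c(sens = g(run$patient_diagnostics$criterion1, "sensitivity"),
                           spec = g(run$patient_diagnostics$criterion1, "specificity")),
            criterion2 = c(sens = g(run$patient_diagnostics$criterion2, "sensitivity"),
                           spec = g(run$patient_diagnostics$criterion2, "specificity"))), 3)
#>            sens  spec
#> criterion1    1 0.696
#> criterion2    1 1.000

run$calcium$CAC[, c("group", "n", "incidence")]
#>        group  n incidence
#> 1     bat_rs 40  0.050000
#> 2 non_bat_rs 46  0.173913
```

Reading the output: of the 1,743 extracted features, 218 survive the
reproducibility filter, 90 the redundancy pruning, and 34 carry nonzero
LASSO coefficients. The SVM radiomics score separates BAT from non-BAT
depots with AUROC 0.98 (training) / 0.92 (internal validation), and the
Youden cutoff lands at 0.375. At patient level, requiring a symmetric
positive pair or a positive mediastinal depot (criterion 2) removes every
false positive on this cohort (specificity 0.70 → 1.00) without losing
sensitivity — the expected behaviour of the symmetry rule. Patients the
model calls BAT-RS positive show roughly a third of the coronary-calcium
incidence of the non-BAT-RS group, matching the generating rates of the
phantom.

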