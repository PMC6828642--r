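# neomyelin

Synthetic quantitative MRI and myelination scoring for the neonatal
brain.

## The problem

Myelination is the imaging biomarker of neonatal brain maturation, and
preterm birth delays it. On conventional T1-/T2-weighted images the
early stages of myelination are hard to see and harder to grade
reliably. Quantitative mapping changes that: a single multi-dynamic
multi-echo (MDME) acquisition — interleaved slice-selective saturation
(flip angle 120°, variable saturation delay TD) and spin-echo readout
(90°/180°, variable echo time TE) — estimates the relaxation constants
T1 and T2 and the proton density PD in every voxel. Myelinating tissue
shortens T1 and T2, so maturation can be read directly off the maps,
and any conventional contrast can be synthesized retrospectively from
them.

`neomyelin` implements this study design end to end as a tested,
fully synthetic pipeline, for methodologists who want to examine the
operating characteristics of map-based myelination scoring: digital
neonatal-brain phantoms with an age-dependent relaxation model, MDME
forward simulation and voxelwise fitting, contrast synthesis, a
seven-region Myelin Total Score, simulated raters, and the cohort
statistics.

## The model in brief

* **MDME signal**, magnitude convention:
  `S(TD, TE) = PD · |1 − (1 − cos(b1·θ_sat)) · e^(−TD/T1)| · e^(−TE/T2)`,
  θ_sat = 120°. Fitting is two-stage: T2 by log-linear regression over
  TE, then T1/PD by profiled least squares on the saturation-recovery
  amplitudes (grid bracket + analytic-derivative bisection, vectorised
  over voxels).
* **Maturation**: each scored region interpolates logistically between
  an unmyelinated (T1 1900 ms, T2 190 ms) and a myelinated (800 ms,
  70 ms) state, with midpoints staggered caudo-cranially; preterm-born
  subjects lag by 2 weeks of maturational age at fixed GAMRI
  (gestational age at MRI).
* **Myelin Total Score (MTS)**: seven regions (medulla oblongata,
  mesencephalon, thalamus, internal capsule, optic tract, frontal and
  central white matter) scored 0–4 each, right hemisphere by default
  (left on right-sided pathology), summed to 0–28. On quantitative maps
  the score is a bin lookup — T1 < 1000 ms scores 4, then 250 ms bins
  down to [1750, 2000) scoring 0; T2 analogously in 25 ms bins from
  100 ms. On synthesized conventional images it is a configurable
  intensity-ratio ladder against surrounding tissue and CSF.
* **Statistics**: two-rater average-measures ICC (absolute-agreement
  and consistency variants, F test on df (n−1, (n−1)(k−1))), Pearson
  correlation of MTS with GAMRI, and ANCOVA of MTS on group (preterm =
  born < 37 + 0 weeks) with GAMRI as covariate, F on df (1, n−3).

## Worked example

```r
library(neomyelin)

ga <- parse_gest_age("25 + 4")
compute_gamri(ga, 94)        # 39 + 0
score_qmap_value(950,  "t1_map")   # 4
score_qmap_value(1100, "t1_map")   # 3
score_qmap_value(1900, "t1_map")   # 0

report <- run_study(study_config())   # ~1 min: 25 subjects, fitted maps
```

With the default configuration (18 preterm + 7 term analyzable
subjects, MDME noise at SNR 50, fitted maps) this prints, via the
report object:

```
included: 25 of 25
T1-map MTS: ICC(A,k)=0.981 [0.946, 0.993], F(24,24)=66.643
Pearson vs GAMRI: r=0.933, n=25, p=1.1e-11
ANCOVA: F(1,22)=10.202, p=0.0042; adjusted means preterm 14.8 vs term 17.9
conventional T1: ICC(A,k)=0.523, r=0.647 (p=0.00), ANCOVA F=1.201 (p=0.29)
```

Reading: the map-based score agrees across the two simulated raters
(ICC above the 0.75 strong-agreement mark), tracks gestational age at
MRI, and detects the built-in 2-week preterm maturational delay after
adjusting for GAMRI (adjusted preterm mean 14.8 vs term 17.9 score
points, p < 0.05). The degraded conventional arm — coarse visual ratio
ladder plus noisier raters — does not (p = 0.29): the map-vs-conventional
sensitivity contrast the design predicts.

Every stage is exposed individually (`simulate_cohort()`,
`build_phantom()`, `mdme_forward()`, `fit_qmaps()`,
`synthesize_contrast()`, `score_qmap_subject()`, `icc_average()`,
`ancova_group()`, …), file I/O helpers read and write NIfTI/CSV/JSON/YAML,
and `inst/scripts/run_study.R` is a thin command-line wrapper
(`--config`, `--seed`, `--outdir`, `--verbose`). A frozen default
configuration ships at `inst/extdata/default_config.yaml`. The methods
vignette (`vignettes/neomyelin-methods.Rmd`) documents the models,
defaults and their rationale.

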