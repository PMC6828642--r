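---
title: "Simulating quantitative-MRI myelination scoring in neonates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating quantitative-MRI myelination scoring in neonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomyelin)
```

## What the package simulates

`neomyelin` is a closed-loop simulation of a neonatal brain-maturation
study built around multi-dynamic multi-echo (MDME) quantitative MRI. A
single MDME acquisition — interleaved slice-selective saturation (flip
angle 120°, variable saturation delay TD) and spin-echo trains (90°/180°
pulses, variable echo time TE) — yields voxelwise estimates of the
longitudinal and transverse relaxation constants T1 and T2 and the proton
density PD. From those maps one can retrospectively synthesize any
conventional contrast (T1w/T2w/PD/IR) and, more importantly for neonates,
read myelination directly off the relaxation constants: myelinating
tissue binds water to macromolecules and shortens both T1 and T2.

The pipeline covers: cohort simulation (gestational ages, scan timing,
exclusion flags), digital brain phantoms with an age-dependent relaxation
model, MDME forward simulation and voxelwise fitting, contrast synthesis,
a seven-region Myelin Total Score (MTS) on both quantitative maps and
synthesized conventional images, two simulated raters, and the statistics
layer: two-rater intraclass correlation (ICC), Pearson correlation of MTS
with gestational age at MRI (GAMRI), and ANCOVA comparing preterm against
term-born neonates with GAMRI as covariate.

## The signal model

The forward MDME signal, in magnitude convention, is

$$S(\mathrm{TD}, \mathrm{TE}) = \mathrm{PD}\,
  \bigl|1 - (1 - \cos(b_1\theta_\mathrm{sat}))\, e^{-\mathrm{TD}/T_1}\bigr|\,
  e^{-\mathrm{TE}/T_2},$$

with $\theta_\mathrm{sat} = 120^\circ$ and $b_1$ the local transmit-field
scale. Excitation and refocusing are treated as ideal 90°/180° pulses —
slice-profile and stimulated-echo effects are real but unparameterized
imperfections, and modelling them would add free constants the rest of
the pipeline could not constrain. $b_1$ enters only through the
saturation term and is fixed at 1 during fitting by default; joint
fitting over a coarse $b_1$ grid is available but off, because the
$B_1$-from-$T_1$ correction used in practice is not specified anywhere
we could anchor it.

Because $1 - 1.5\,e^{-\mathrm{TD}/T_1}$ changes sign at
$\mathrm{TD} = T_1 \ln 1.5$, the magnitude signal is *not* monotone in
TD: it falls to the null point and recovers toward PD. The fitter and the
tests are written against this fold; monotonicity in TD only holds on
the recovery branch.

The default protocol grid is four saturation delays (150, 700, 1900,
4000 ms) by five echoes (13, 35, 60, 100, 140 ms), with TE 13 ms and TR
3309 ms fixed by the acquisition protocol and the remainder configurable:
the published protocol does not state the full grid, so it is
configuration with documented defaults.

### Fitting

`fit_qmaps()` is a two-stage estimator. T2 and the echo-free amplitude
come from a log-linear regression over TE within the longest saturation
delay (where saturation recovery is most complete); amplitudes at every
delay follow by projecting each echo train onto the fitted decay. T1 is
then obtained by profiled least squares on the amplitude-vs-TD curve:
for a candidate T1 the optimal amplitude (hence PD) is a closed-form
linear solve, so the problem is one-dimensional. A log-spaced grid scan
brackets the optimum and a bisection on the analytic derivative of the
profiled objective refines it; a golden-section fallback covers voxels
whose bracket straddles the magnitude kink. Everything is vectorised
over voxels, which keeps a 25-subject study with roughly 45,000 brain
voxels per subject within a few seconds of fitting per subject.
Degenerate voxels (all-zero or non-finite signal) and estimates landing
on a parameter bound (T1 ∈ [100, 6000] ms, T2 ∈ [10, 3000] ms,
PD ∈ (0, 120]) are flagged in the `converged` map rather than silently
altered.

Noiseless round-trips through the forward model recover all three
parameters to machine precision; at SNR 50 (Rician noise,
$\sigma = \mathrm{PD}/50$, the default study condition) the median
relative T1 error over the scoring range is just under 2%.

## The phantom and the maturation model

Phantom geometry is deliberately schematic: the seven scored regions —
medulla oblongata, mesencephalon, thalamus, internal capsule, optic
tract, frontal white matter, central white matter — are mirrored boxes
inside an ellipsoidal brain with a cortical gray-matter shell,
unmyelinated white-matter interior and bilateral ventricular CSF, on a
64×64×32 grid at 2 mm isotropic. Scoring depends only on ROI statistics
(the regional median), not on morphology, so anatomical realism would
buy nothing here; this is stated as a limitation for any use beyond
score-level simulation (no partial-volume modelling, no cortical
folding).

Each scored region interpolates logistically between an unmyelinated
state (T1 1900 ms, T2 190 ms) and a myelinated state (T1 800 ms, T2
70 ms) as a function of maturational age $g$:

$$T_1(g) = T_1^u - (T_1^u - T_1^m)\,\sigma\!\left(\frac{g - g_{50}}{s}\right).$$

Midpoints are staggered caudo-cranially (medulla 31 w, mesencephalon
33.5 w, thalamus 36 w, internal capsule 38.5 w, optic tract 41 w,
central white matter 43.5 w, frontal white matter 46 w; slopes 2–3 w),
mirroring the known maturation sequence: brainstem structures are
already myelinated at the expected due date, frontal white matter is
not. The even staggering also keeps the aggregate MTS approximately
linear in age across the observed GAMRI range, which matters for the
ANCOVA's linear adjustment. Under these defaults the medulla T1 is
below 1000 ms (top scoring bin) at 42 weeks while frontal white matter
sits in the 1750–2000 ms bin at 38 weeks.

Three stochastic components ride on top:

* **Voxel jitter** — multiplicative Gaussian, CV 2% by default —
  emulates within-region heterogeneity. Regional medians average it
  away almost entirely.
* **Between-subject maturational variability**, SD 0.9 weeks at fixed
  GAMRI. Real neonates scanned at the same corrected age differ in
  myelination stage; without this term the simulated scores are nearly
  deterministic functions of GAMRI, and the ANCOVA's F test inherits
  the staircase lack-of-fit of a discretised score, inflating its
  type-I rate well above nominal. With it, the residuals are dominated
  by smooth subject-level noise and the test is calibrated (verified by
  a 200-replicate null simulation in the test suite).
* **Preterm maturational delay**, 2 weeks by default: preterm-born
  subjects at a given GAMRI behave like term subjects 2 weeks younger.
  Near a transition midpoint this is ≈275 ms of T1, about one scoring
  bin — the constructed group effect the ANCOVA is meant to detect.

## Scoring

On quantitative maps, a region's representative value is the voxel
median of its ROI in the scored hemisphere, binned with half-open
`[low, high)` edges: T1 < 1000 ms scores 4, then 250 ms bins down to
[1750, 2000) scoring 0 (T2: < 100 ms scores 4, 25 ms bins to [175, 200)).
Values at or above the top edge also score 0 — the criteria leave the
upper tail open, and less mature tissue cannot score higher. The shared
bin endpoints belong to the upper bin; the published criteria print
closed ranges with shared endpoints and do not say which side owns the
boundary, so this is a documented convention, not an inference. The
seven region scores sum to the MTS (0–28). Scoring reads the right
hemisphere by default and switches to the left for right-sided
pathology; bilaterally devastated subjects are excluded by the
inclusion filter (motion artifact, bilateral devastation, or both —
doubly flagged subjects are excluded once under a combined reason).

On synthesized conventional images (T1w SE TR 400/TE 15; T2w TSE TR
3000/TE 140, matching the conventional protocol), the ordinal visual
criteria ("slightly/clearly/considerably hyper- or hypointense to
surrounding tissue / CSF") are operationalized as a ladder on two
ratios: ROI/surround and ROI/CSF for T1w, inverted for T2w. A level is
awarded when both ratios pass its thresholds; the score is the highest
level met. Two design choices matter:

* The default thresholds are **coarse** (T1w ROI/surround 1.5, 2.0,
  2.6, 3.3): a structure reads as frankly hyperintense only near full
  myelination, so intermediate states stay at the bottom of the ladder.
  This encodes the clinical observation the study design rests on —
  early myelination is hard to see on conventional neonatal images, and
  with finer thresholds the operationalized conventional score would be
  nearly as sensitive as the quantitative bins, which real conventional
  reading is not.
* Thresholds are **modality-specific** (T2w: 2.0, 3.0, 4.5, 6.5). The
  ordinal steps correspond to roughly equal increments of log signal,
  and the heavily T2-weighted TSE image spans a far wider signal range
  than a short-TR T1w spin echo, so equal perceptual steps are larger
  ratios on T2w. With shared thresholds the T2w arm would be spuriously
  sensitive.

Both ladders are plain configuration (`conventional_ladder()`), as are
the bins (`score_bins()`).

Simulated raters perturb each region score by ±1 with a per-region miss
probability, then clamp to 0–4. Defaults are 0.30 for map reading and
0.40 for conventional reading; the map value is anchored to the
reported interrater agreement of map-based scoring (average-measures
ICC near 0.87 — a reliability far below what error-free scoring would
produce), and conventional reading is noisier still, consistent with
its reported near-zero concordance.

## Statistics

`icc_average()` implements the two-way ANOVA decomposition with both
average-measures variants — absolute agreement
$(\mathrm{MSR}-\mathrm{MSE})/(\mathrm{MSR}+(\mathrm{MSC}-\mathrm{MSE})/n)$
and consistency $(\mathrm{MSR}-\mathrm{MSE})/\mathrm{MSR}$ — because
"average measured ICC" in common statistical software may denote either;
both are reported and neither is asserted as *the* published variant.
The F test ($\mathrm{MSR}/\mathrm{MSE}$, df $(n-1, (n-1)(k-1))$) is
identical across variants; for 25 subjects and two raters the dfs are
(24, 24). Confidence bounds follow McGraw & Wong (exact F bounds for
consistency; the Satterthwaite single-measures interval mapped through
Spearman–Brown for agreement). Constant ratings leave the ICC undefined
and are flagged, not fabricated.

`ancova_group()` is the nested-OLS F test — full model
`y ~ 1 + covariate + group` against `y ~ 1 + covariate`,
$F = (\mathrm{RSS_{red}} - \mathrm{RSS_{full}})/(\mathrm{RSS_{full}}/(n-3))$
on df (1, n − 3); with 25 subjects, (1, 22). No group×covariate
interaction is fitted, matching the stated analysis. Term-born is the
reference level; adjusted means are predictions at the grand covariate
mean. A response that is exactly collinear with the covariate yields
F = 0 by an explicit guard (the ratio is otherwise 0/0), and a covariate
collinear with the group indicator is a hard error. Significance is
two-sided at α = 0.05 throughout, with ICC ≥ 0.75 labelled strong
agreement; no multiplicity correction is applied, matching the analysis
this emulates.

## What the default study shows — and what it cannot

```r
report <- run_study(study_config())
```

simulates the default 25-subject cohort (18 preterm, 7 term; preterm GA
25 + 4 ± 1 + 6 w scanned at term-equivalent age, term GA 39 + 6 ± 1 + 2 w)
through the full fitted-map path in about a minute. Under the default
delayed-maturation condition, map-based MTS detects the group difference
(ANCOVA on df (1, 22), adjusted preterm mean below term) and correlates
positively with GAMRI, while the degraded conventional arm does not —
the qualitative contrast the study design predicts. The test suite
verifies the two calibration properties behind that claim with
200-replicate batches on ground-truth maps: type-I rate within the
binomial 99% band of α = 0.05 under a null configuration
(`preterm_delay_weeks = 0`), ≥80% power for map-based scoring and <50%
for conventional scoring under the default configuration.

Problem sizes used by the tests are the package defaults — 64×64×32
phantoms for study-level properties, 32×32×16 for structural unit tests,
500 voxels for the SNR benchmark — chosen to exercise the full pipeline
at cohort scale.

What passing these simulations does **not** show: that real neonatal
cohorts meet the generator's assumptions. The phantom has no partial
voluming, motion, or B0/B1 structure beyond an optional smooth gradient;
the maturation model's logistic form, bounds and midpoints are plausible
but synthetic; rater noise is symmetric and independent across regions,
which real raters are not; and the conventional-image ladder is an
operationalization of an inherently visual judgment. The simulation
demonstrates that the *pipeline* — scoring rules, hemisphere logic,
exclusion accounting, ICC/ANCOVA machinery — behaves correctly and that
the study design has the claimed operating characteristics under stated
conditions, not that those conditions hold in vivo.

## Numerical conventions

* Gestational ages are stored as whole days and rendered as
  `weeks + days`; decimal weeks are always derived. The preterm cutoff
  is `< 37 + 0` (exactly 37 + 0 is term).
* All bin and class intervals are half-open `[low, high)`.
* Truncated-normal draws use inverse-CDF sampling, so every stage is
  reproducible from the master seed; per-stage seeds are derived by
  fixed offsets.
* Gestational-age sampling is truncated to 22–42 w at birth and
  postnatal intervals to ≥0 days for physiologic plausibility.
* The fitter never clamps silently: bound hits and degenerate voxels
  are flagged per voxel.
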