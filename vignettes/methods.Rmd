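---
title: "Source-based inflammetry and cross-modal connectivity analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-based inflammetry and cross-modal connectivity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Activated microglia — the brain's innate immune response — can be imaged in
vivo with TSPO PET tracers, and Alzheimer-spectrum patients show elevated
binding in hippocampal and temporal cortex. `inflammetry` implements a
three-stage multivariate analysis linking that neuroinflammation signal to
resting-state functional connectivity and to cognitive impairment, in a
cohort of 28 amyloid-positive AD/MCI patients and 14 matched controls:

1. **Source-based inflammetry (SBI).** The subject-by-voxel matrix of PET
   binding-potential maps, masked to gray matter, is decomposed by spatial
   ICA into independent spatial sources and a subject-by-component mixing
   (loading) matrix. A component is carried forward only if its loadings
   differ between groups (robust permutation test) *and* correlate
   negatively with total gray matter in the patient stratum — the
   group-differentiating, atrophy-associated component.
2. **First-level cross-modal regression.** Whole-brain pairwise Pearson
   connectivity (78 connections among 13 default-mode, frontoparietal and
   subcortical nodes) is regressed onto the selected component's loadings
   by multiple linear regression with Ledoit–Wolf shrinkage regularization.
   The fitted linear combination per subject is the *brain score*; each
   connection's correlation with the brain scores is its *structure
   coefficient*. Model fit is validated by 5-fold cross-validation with
   1,000 random re-partitions (median R), and inference is by label
   permutation.
3. **Second-level interaction model.** A robust regression of a cognitive
   composite (first principal component of MMSE, ACE-R and RAVLT) on
   brain score, group, their interaction, and covariates of no interest
   (age, sex, head-motion RMS, total gray matter), with within-group
   post hoc correlations.

Raw imaging for such a cohort is rarely shareable, so the package pairs the
analysis with a synthetic-cohort generator that plants every effect the
analysis is supposed to find; the test suite is a parameter-recovery study.

# The synthetic generator: what it emulates and what it does not

`sim_config()` fixes the study conditions: 28 patients / 14 controls, five
spatial sources on a 20×20×20 voxel grid, 13 nodes in three networks
observed for 263 volumes at TR = 2.43 s (269 acquired minus 6 dummy
volumes), and three cognitive tests.

**PET maps.** Sources are 3-D Gaussian blobs (unit maximum, SD two voxels)
at random centers spaced at least five blob SDs apart (relaxed toward three
SDs on deliberately cramped test grids), which keeps pairwise spatial
correlations below 0.2 and makes them genuinely independent and compact —
the property the real data-driven sources are assumed to have. Maps are
`loadings %*% sources` plus Gaussian voxel noise. Loadings are standard
normal per component; the target component (the third where five exist)
gains `group_effect = 1` SD in patients. The voxel-noise SD of 0.1 (10:1
peak SNR) reflects smoothed, averaged binding maps; it was chosen during
the generator's own calibration so that the planted five-source structure
is recoverable by the decomposition it feeds.

**Connectivity.** Each subject's latent inter-node correlation matrix is a
fixed baseline (within-network r ≈ 0.4–0.5, weak between-network coupling,
mildly anticorrelated default-mode–putamen block) shifted on designated
connections by `coupling × weight × centered target loading`, clipped to
±0.95 with nearest-correlation repair (logged) if needed. Weights are +0.3
on default-mode–hippocampus connections and −0.3 within the default-mode
network, matching the direction of the group effects the analysis is
designed to detect. Time points
are i.i.d. multivariate normal draws: no hemodynamics, no temporal
autocorrelation, no scanner noise — downstream stages consume only the
correlation estimates, and T = 263 i.i.d. samples give sample correlations
the right sampling error for that estimate.

**Cognition.** A latent factor carries a fixed patient deficit plus
`interaction_slope × brain score` in patients only, with subject-level
noise; the three tests observe the standardized factor through test-specific
noise of SD sqrt(3/7), which makes the inter-test correlation 0.7 and hence
the first principal component's variance share exactly (1 + 2·0.7)/3 = 80%.
The test noises are orthogonalized against the latent factor in-sample, so
the 80% share is structural rather than fluctuating with the draw — the
calibration the analysis anchors on. Subject-level noise defaults to 0.10:
most measurement error is placed at the test level, and the default keeps
the covariate-adjusted interaction test at roughly 90% power at the planted
slope of −0.5. A consequence is that the synthetic within-patient
correlation between composite and brain score (≈ −0.8) is stronger than the
−0.5 typical of real cohorts; the planted effect is deliberately clean.

**Covariates.** Age, sex, education and motion are drawn from plausible
cohort distributions and are independent of everything (the design is
matched); total gray matter declines with the target loading in patients
(slope 15–25 binding-loading units per 20 SD; default 20 with noise SD 20),
planting the atrophy association the selection rule requires. That same
association makes the total-GM covariate partially collinear with the
interaction regressor at the second level — as in real cohorts — which is
the binding constraint on interaction power.

What passing tests therefore show: the pipeline recovers planted sources,
model order, the selected component, connectivity coupling and the
interaction sign/magnitude under clean, correctly specified conditions at
the study's n. They do not show robustness to hemodynamic confounds,
motion artifacts, non-Gaussian binding distributions or model
misspecification.

# Methods and numerical choices

**Nuisance regression and filtering.** One GLM per node: intercept, linear
trend, the 24-parameter motion expansion (6 realignment parameters, their
first differences, squares of those 12), white-matter and CSF means
(voxels with tissue probability > 0.7) with differences and squares, and a
discrete cosine basis restricted to frequencies *outside* 0.0078–0.1 Hz
(DCT-II frequency k/(2·T·TR), up to Nyquist), so bandpass and nuisance
removal happen in a single projection. All-zero blocks are dropped with a
message; rank deficiency is resolved by QR with dropped labels logged.
Head motion is summarized as the RMS of volume-to-volume displacement with
rotations mapped to arc length on a 50 mm sphere — a documented convention.

**Group mask.** A voxel enters if the across-subject *mean* gray-matter
probability strictly exceeds 0.3; this reconciles the two natural readings
of "probability larger than 0.3 across all individuals" into one rule.

**Model order (MDL).** Wax–Kailath-style minimum description length on the
eigenspectrum of the subject-space covariance (v voxels as observations),
candidates 1..n−1; eigenvalues are floored at 1e−12 of the largest so
rank-deficient stacks resolve to their true rank. A flat spectrum returns 1
with a warning.

**Spatial ICA.** Rows (subject maps) are centered; PCA whitening to k
components in subject space; fixed-point ICA with the logcosh contrast and
deflation, tolerance 1e−8, at most 500 iterations per component,
deterministic given the seed with two fallback seeds before erroring.
Loadings are recovered by least squares, so the rank-k reconstruction
equals the PCA truncation exactly. Sources are standardized to unit
variance (population convention) over masked voxels and sign-fixed to
positive skewness, so a higher loading always means higher binding in the
source's hot spots.

**Robust regression.** All group-difference and brain-behavior fits use
Huber IRLS (tuning constant 1.345·MAD, the 95%-efficiency convention),
implemented on `lm.wfit` for speed inside permutation loops and verified
against `MASS::rlm` in the tests; on exactly linear data it reduces to OLS,
which is what makes the noiseless-recovery contracts exact. Standard
errors use the Huber sandwich with a small-sample df correction; its
type-I error is verified at ~0.05 by simulation.

**Grubbs screening.** Iterative two-sided Grubbs at α = 0.05 on the
selected component's loadings before the first-level fit; flagged subjects
are excluded with a message. The critical value is the standard
t-quantile closed form; the tests cross-check decisions against a
Monte-Carlo null of the max studentized deviate.

**Ledoit–Wolf shrinkage.** The analytic well-conditioned estimator
ρμI + (1−ρ)S with S the MLE covariance of standardized predictors; ρ is
the analytic optimum (verified to 13 digits against an independent
implementation) or a fixed value. Predictors are z-scored before
shrinkage; during cross-validation the standardization and the covariance
are learned on training folds only.

**Cross-validation and permutation inference.** R is defined as the
Pearson correlation between pooled out-of-fold predictions and observed
loadings; the reported statistic is the median over `n_repeats` random
partitions. The model-level p-value compares that median with its
distribution under label permutation, using the *same* partitions and
number of repeats per permutation. This is affordable because, for fixed
predictors and partition, out-of-fold predictions are linear in the
response (the shrinkage covariance does not involve it), so each
(repeat, fold) contributes one precomputed hat block applied to all
permuted responses at once. Connection-level p-values compare structure
coefficients with their full-sample permutation distribution, then
Benjamini–Hochberg across the 78 connections.

**Covariate placement.** Age, sex, motion and total gray matter enter the
second-level model as regressors; the first-level fit sees the
connectivity and loadings directly (the first-level nuisance control is
the time-series GLM). A configurable option residualizes the covariates
out of both sides before the first-level fit instead — note that with the
planted gray-matter–loading association, first-level residualization on
total gray matter removes most of the interaction signal the second level
tests, which is why it is not the default. Brain scores entering the
second level come from the full-sample fit; cross-validation only
validates fit quality.

**Second level.** Group is coded patients = 1; brain scores are centered
before forming the interaction, so without covariates the interaction
coefficient equals the difference of the two within-group slopes exactly
(checked numerically). The robust fit is the default, OLS an option.

# Design decisions that were genuinely open

- "Expansions of realignment parameters" admits several orders; the
  24-parameter set is used.
- The bandpass mechanism is named (DCT in the GLM) but not the column set;
  stop-band columns below the low cut and above the high cut are included.
- Whether connectivity entering the first level is Fisher-transformed is
  unstated; raw Pearson r is used there (matching the stated measure),
  while the univariate group statistics use Fisher z before pooling.
- Group-ICA toolboxes differ in their rotation; fixed-point logcosh
  deflation is pinned, with seeds controlled.
- A single headline "model r" is ambiguous between in-sample and
  cross-validated; both are computed and labeled.
- Whether education entered as a covariate is unstated (the design is
  education-matched); it is not included.
- The multiple-comparison rule for the connection map is unstated; FDR
  across 78 connections, configurable.

# Problem sizes and reduced settings

Defaults match the analysis scale: 1,000 CV repeats, 5,000 model
permutations, 10,000 label shuffles for the loading group test. The test
suite's Monte-Carlo studies run 50–200 replicates at 100 CV repeats and
500–999 permutations with fixed replicate seeds — sizes chosen so the whole
recovery study is a single-CPU desk run while keeping permutation p-value
resolution (≥ 1/1000) well below the α = 0.05 decisions they feed.

# Known limitations

- One cohort-level failure mode is inherent to the planted design: at the
  pinned group effect of 1 SD with n = 28/14, the loading group test has
  ~85% power, so roughly one synthetic cohort in seven yields no
  selectable component. The pipeline treats that as the documented
  "no-selection" halt rather than silently proceeding.
- The generator's cognition effect is cleaner than real data's (see
  above); absolute second-level t values run larger than real cohorts
  would give, and only sign and significance patterns are comparable.
- i.i.d. time points mean the effective temporal df equals T; real fMRI
  autocorrelation would widen connectivity sampling error.
- The total-GM covariate is collinear with the interaction by design;
  estimates of the interaction with covariates are unbiased but less
  precise, exactly as in the real analysis.
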