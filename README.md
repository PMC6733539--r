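# inflammetry

Links in-vivo neuroinflammation, resting-state functional connectivity and
cognitive impairment in an Alzheimer's-spectrum cohort, as a tested,
reusable R pipeline. It is aimed at neuroimaging researchers who want the
full two-level multivariate analysis — source-based inflammetry of TSPO PET
binding maps, shrinkage-regularized connectivity regression, and a
brain-score × group interaction model on a cognitive composite — together
with a synthetic-cohort generator that makes every stage testable without
access to raw imaging data.

## The analysis

Given subject-level PET binding-potential maps, node time-series and a
cohort table (28 AD/MCI patients, 14 controls):

1. **Source-based inflammetry (SBI).** The subject × voxel matrix *X*
   (gray-matter masked) is decomposed by spatial ICA,
   *X ≈ A S*, into spatially independent source maps *S* (component ×
   voxel) and a mixing matrix *A* of per-subject loadings. The model order
   is chosen by an MDL criterion on the subject-space eigenspectrum. The
   component taken forward is the unique one whose loadings (i) differ
   between groups (Huber-robust regression, permutation p) and (ii)
   correlate negatively with total gray matter in patients.
2. **First-level cross-modal regression.** With connectivity
   *X* (subject × 78 Pearson correlations among 13 nodes, z-scored) and
   selected loadings *y*, the weights are
   *w = Σ\*⁻¹ cov(X, y)* where *Σ\* = ρμI + (1−ρ)S* is the Ledoit–Wolf
   well-conditioned covariance with analytic ρ. Brain scores are *Xw*;
   structure coefficients are cor(*Xⱼ*, *Xw*). Fit quality is the median
   Pearson *R* between pooled out-of-fold predictions and *y* over 1,000
   random 5-fold partitions; model and connection significance come from
   label permutation (FDR across connections).
3. **Second level.** The first principal component of MMSE, ACE-R and
   RAVLT (sign-fixed so higher = better) is regressed on centered brain
   scores, group, their interaction, and age, sex, motion RMS and total
   gray matter, with a Huber-robust fit; within-group correlations are
   reported post hoc.

Time-series cleaning uses one GLM per node: trend, 24-parameter motion
expansion, white-matter/CSF signals with derivatives and squares, and a
discrete-cosine stop-band basis implementing the 0.0078–0.1 Hz bandpass
simultaneously with nuisance regression.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R 3      # cohort, maps, time-series
Rscript analysis/02_connectivity.R    # cleaning + connectivity
Rscript analysis/03_sbi.R 3           # ICA, component tests, selection
Rscript analysis/04_crossmodal.R 3    # shrinkage MLR + CV + permutation
Rscript analysis/05_second_level.R    # cognitive PCA + interaction model
```

A run at seed 3 prints, stage by stage:

```
design columns: 146 (144 stop-band DCT)
18 of 78 connections differ between groups after FDR
MDL model order: 5
selected component: IC4 (group t = 3.85, permutation p = 9e-04,
  patient GM r = -0.65)
in-sample r = 1; cross-validated median R = 0.98 (permutation p = 2e-04)
20 connections survive FDR at 0.05
cognitive PC1 explains 80% of variance (loadings 0.58, 0.58, 0.58)
brain-score x group interaction: t = -4.01, p = 0.00032
post hoc: patients r = -0.87 (p = 2.6e-09); controls r = 0.18 (p = 0.54)
```

Reading: the decomposition finds the planted five-source structure and
selects the component whose loadings separate patients from controls and
track atrophy; whole-brain connectivity predicts those loadings far above
chance under cross-validation; and the connectivity pattern's expression
relates to worse cognition specifically in patients — the negative
interaction, absent in controls. Because the planted group effect sits at
~85% detection power (1 SD at n = 28/14), some seeds legitimately end in
the pipeline's "no-selection" halt, and single-seed statistics vary; the
test suite characterizes the distribution over 50 replicates. The same
pipeline is available in one call as
`run_pipeline(pipeline_config(seed = 3))`, which also writes a manifest of
file digests for reproducibility checks.

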