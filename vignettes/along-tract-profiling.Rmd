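---
title: "Along-tract diffusion profiling: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract diffusion profiling: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alongtract)
```

`alongtract` implements a complete along-tract diffusion-tensor analysis of a
curved white-matter bundle — the anterior cingulum is the motivating case —
from the raw diffusion-weighted signal down to the diagnostic statistics that
compare a patient group against controls. Because clinical diffusion MRI is
rarely shareable, the package carries its own study generator: a C-shaped
bundle phantom with a controlled lesion, and a two-group subject cohort with
prescribed per-parameter distributions. Everything downstream (tensor fit,
tractography, landmark normalization, group statistics) operates identically
on simulated and real inputs of the supported formats (NIfTI + bvec/bval,
TrackVis `.trk`, JSON landmarks/ROIs, CSV cohort tables).

## The diffusion tensor model

Each voxel's signal across encoding directions is modeled as
$S(\mathbf{g}, b) = S_0 \exp(-b\, \mathbf{g}^\top D \mathbf{g})$, with $D$ a
symmetric positive-definite $3 \times 3$ tensor in units of
$10^{-3}\,\mathrm{mm^2/s}$ (so a physiologic mean diffusivity is about 0.8).
`fit_tensor()` estimates the seven parameters ($\ln S_0$ and six tensor
elements) per voxel by ordinary least squares on the log-signal. The
log-linear fit is exactly invertible on noiseless data, which the test suite
exploits as a round-trip oracle; weighted and nonlinear variants are
deliberately out of scope. Eigenvalues $\lambda_1 \ge \lambda_2 \ge
\lambda_3$ yield the four scalar parameters:

* FA $= \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - \bar\lambda)^2} / \sqrt{\sum_i \lambda_i^2}$
* MD $= \bar\lambda$, aD $= \lambda_1$, rD $= (\lambda_2 + \lambda_3)/2$

Eigenvalues are used raw — a voxel with a negative eigenvalue is flagged, not
clipped, so noise-induced degradation stays visible. The eigendecomposition
is a vectorized closed form (trigonometric solution of the characteristic
polynomial; principal eigenvector from $(A - \lambda_2 I)(A - \lambda_3 I)$),
cross-checked in the tests against `eigen()` on random tensors. The
eigenvector sign convention (first nonzero component positive) makes all
derived outputs deterministic.

## The bundle phantom

`make_bundle_phantom()` builds a half-torus ("C"-shaped) tube in a $64^3$
grid of 2 mm isotropic voxels, mimicking the geometry and acquisition of a
1.5–3 T clinical protocol: 48 encoding directions (spherical-Fibonacci
layout; the classic dual-gradient set at exactly 6 directions, where the
Fibonacci layout is tensor-degenerate) at $b = 800\,\mathrm{s/mm^2}$ plus one
$b=0$ volume. Inside the tube, tensors are axially symmetric with the
principal axis tangent to the centerline; `eigenvalues_for_fa_md()` solves
the axially symmetric eigenvalues exactly for any target FA $< 1$ at a given
MD. Outside, diffusion is isotropic at a gray-matter-like 0.7. Noise is
Rician: independent $N(0, (S_0/\mathrm{SNR})^2)$ perturbations of two
quadrature channels, then the magnitude — so all simulated intensities are
positive and low-SNR FA acquires the well-known positive bias (about +0.01
at SNR 20 for FA 0.4 under this protocol, measured by the Monte-Carlo test).
SNR is defined on the $b=0$ signal; the default of 20 is a package choice of
a typical clinical value, not a reported one.

The arc is divided into anterior, dorsal, posterior and ventral segments
whose boundaries sit at the landmark arc fractions, and five landmarks LM1–
LM5 sit at arc fractions 0.05/0.30/0.55/0.80/0.95. Placing the anterior
segment exactly on the LM1–LM2 interval makes the "LM12 segment mean" an
unbiased readout of the anterior lesion. In the patient condition only the
anterior FA is degraded (0.39 vs 0.47 at matched MD 0.81), the along-tract
signature the analysis is designed to detect. In real anatomy the landmarks
are placed manually relative to the corpus callosum; the phantom has no such
reference, so prescribed arc fractions stand in for them.

What the phantom does **not** emulate: crossing fibers, partial-volume
mixtures at tissue interfaces, susceptibility/eddy distortion, motion, and
anatomy beyond a single tube. Passing tests therefore demonstrate
correctness of the estimation chain under the single-tensor model, not
robustness to those real-data effects.

## Tractography

`track()` is deterministic FACT: one seed per voxel with FA $\ge$ 0.2,
bidirectional Euler propagation (step = half a voxel) along the
nearest-voxel principal eigenvector, sign-aligned with the previous step;
termination on leaving the volume, entering a voxel below the FA threshold,
or exceeding the 45° angular threshold between consecutive steps. There is
no length criterion; a `max_steps` cap (default 2000) exists only because a
torus-like synthetic field supports closed orbits. The original clinical
workflow used TrackVis, whose exact propagation is not published; FACT with
Euler steps is the simplest faithful stand-in, which is why streamline
*counts* are never compared across implementations — only proportions and
geometry. One discretization property is worth knowing: on a voxelized
curved tube, orbits in the outer shell (within about one voxel of the
boundary) terminate early wherever their containing voxel's center falls
outside the tube. The tract-spanning bundle — streamlines that project all
five landmarks in order — runs the full analytic arc length to within 1%,
while the mean over all seeds is pulled down by these truncated peripheral
tracks (ratio about 0.78 at the default geometry).

`select_bundle()` implements the manual-tractography idiom: keep streamlines
that intersect every include ROI and no exclude ("NOT") ROI, with
nearest-voxel membership. Order is preserved, and adding NOT ROIs can only
shrink the bundle.

## Landmark-normalized profiles

The profiling stage follows the quantitative-tract-evaluation idea —
extracting a diffusion parameter in each cross-section along the bundle —
which the original software describes only functionally. The concrete
algorithm here is this package's definition of it:

1. `project_landmarks()` maps each landmark to the arc length of its nearest
   point on each streamline (capture radius 10 mm). Streamlines are put in a
   canonical orientation (LM1 end first); those whose five projections are
   not strictly increasing are excluded and counted.
2. `normalize_and_average()` warps each streamline's arc length
   piecewise-linearly so landmark $i$ sits at normalized position $i$,
   resamples at `k_per_segment` (default 20) equal steps per segment, and
   samples the scalar map at the resampled points. A "cross-section" is the
   set of resampled points sharing a warped coordinate, not a geometric
   plane — robust for curved bundles.
3. Per-position means across streamlines form the subject profile;
   `segment_mean()` averages positions within a landmark interval (LM12 for
   the anterior comparison). Group profiles average subject profiles, with
   SE across subjects — the convention used for the group mean ± 1 SE plot.

Scalar maps are sampled at the nearest voxel by default. Trilinear
interpolation is available (`interp = "trilinear"`), but at a sharp tissue
boundary it mixes background into every sample within one voxel of the edge
and dilutes a 3-voxel-radius tube's profile by 10–15%; nearest-voxel
sampling is also consistent with FACT's own direction lookup. Whether the
original method averaged within subject before or after cross-section
binning is unstated; this package bins first, then averages, and treats that
as part of its definition.

## Cohort simulation and the statistics battery

`simulate_cohort()` draws per-subject parameter values independently from
group-specific normal distributions; the defaults are the published group
summaries of the motivating study (22 controls vs 14 patients; twelve
imaging parameters). Covariates: age $\sim N(68, 8^2)$ truncated to 38–82,
sex Bernoulli(1/2), education $\sim N(10, 2^2)$ years — chosen to bracket
the study's demographics; they matter only as regression covariates. Each
subject has a private random substream derived from (master seed, group,
index), so enlarging a cohort never reshuffles existing subjects.

The battery in `discrimination_table()` and friends mirrors a clinical
discrimination analysis:

* **Cohen's d** uses the *average*-SD denominator $|m_1 - m_2| / ((s_1 +
  s_2)/2)$. This is deliberate: it reproduces the published effect sizes for
  five of the eight white-matter rows exactly at printed precision (the
  remaining three agree within rounding of the printed means), whereas the
  pooled-SD convention does not.
* **Student's t** is the pooled-variance two-tailed test, with the primary
  six-parameter family Bonferroni-corrected to $\alpha = 0.05/6 = 0.008$;
  secondary analyses stay at 0.05.
* **ROC AUC** is concordant-pair counting (midranks; half credit for ties),
  oriented per parameter from the group-mean direction so reported AUCs are
  $\ge 0.5$; significance against 0.5 via the tie-corrected Mann–Whitney
  normal approximation, so `roc_auc()` and `mann_whitney()` satisfy
  $\mathrm{AUC} = U / (n_1 n_2)$ identically.
* **Youden cut-offs** sweep midpoints between adjacent unique scores; first
  maximum on ties.
* **Logistic classification** (`logistic_enter()`) enters the parameter with
  age, sex and education at once, fits by IRLS (`glm`), classifies at fitted
  probability 0.5, and flags complete separation rather than reporting a
  divergent fit.
* **McNemar** is the exact binomial on discordant pairs — the only
  convention consistent with two-sided p-values of 0.03125 and 0.0625 for
  (6, 0) and (5, 0) discordant patterns.
* **ICC(2,1)** (two-way random, absolute agreement, single measures) comes
  from explicit ANOVA mean squares with the standard F-based interval.

## The pipeline and its numerical choices

`run_pipeline()` chains cohort simulation, the statistics battery, a
per-subject imaging arm (each subject gets a phantom whose anterior FA is
drawn from its group's distribution, then tensor fit, tracking, ROI
selection and FA profiling), and parameter recovery, writing every artifact
plus a manifest (config, seed, versions, MD5 checksums, per-stage exclusion
counts) to the run directory. Downstream stages always read the cohort from
its CSV artifact, which makes cached stage reruns bit-identical. A single
master seed fans out to named substreams per stage and subject.

Problem sizes are chosen so a full default run — 36 subjects at $64^3$
voxels and 49 volumes each — completes in about two minutes on one core;
the test suite uses a $44^3$ phantom where only geometry matters.
Recovery of the group contrast is assessed against the *realized*
per-subject generating values: with 14 patients and a between-subject SD of
0.053, the cohort mean itself has SE 0.014, so comparing to the nominal
group mean would mostly measure cohort sampling noise rather than pipeline
accuracy. At SNR 20 the pipeline recovers group LM12 FA means within about
0.015 of the realized generating means (Rician bias dominates), and places
the anterior transition within one profile grid step of the true landmark-2
boundary.

## Known limitations

* Single-tensor, single-fiber model throughout; no crossing-fiber handling.
* FACT with nearest-voxel directions truncates peripheral orbits of curved
  tubes (see above); absolute streamline counts are implementation-specific.
* The profile's nearest-voxel sampling trades sub-voxel smoothness for
  boundary robustness; on smooth fields both samplers agree (tested).
* Published clinical results that depend on the unavailable patient data
  (sample AUCs, logistic coefficients, sensitivity/specificity pairs, rater
  ICCs) are covered only by model-level compatibility checks — e.g. the
  analytic normal-model AUC for left radial diffusivity, 0.956 — never
  reproduced.
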