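# alongtract

Along-tract diffusion-tensor profiling of a curved white-matter bundle, and
the diagnostic statistics that compare a patient group against controls.

Diffusion tensor imaging (DTI) summarizes water diffusion per voxel as a
symmetric tensor **D**, from whose eigenvalues the standard scalar
parameters follow — fractional anisotropy (FA), mean diffusivity (MD), axial
(aD = λ₁) and radial (rD = (λ₂+λ₃)/2) diffusivity. In neurodegenerative
disease, along-tract analysis asks a sharper question than whole-tract
averages: *where* along a bundle (here, a cingulum-like C-shaped tract) does
white-matter integrity change, and how well do those localized parameters
discriminate patients from controls compared with cortical atrophy
measures?

`alongtract` implements the full chain for that question:

* **Simulation** — a C-shaped DWI bundle phantom (48 directions at
  b = 800 s/mm², 2 mm isotropic voxels, Rician noise) with a controllable
  anterior lesion, plus a two-group subject cohort with prescribed
  per-parameter means/SDs (`make_bundle_phantom()`, `simulate_cohort()`).
* **Tensor estimation** — log-linear least-squares fit and closed-form
  scalar maps with the principal eigenvector field (`fit_tensor()`,
  `scalar_maps()`).
* **Tractography** — deterministic FACT streamlining with FA threshold 0.2,
  angular threshold 45°, no length criterion, and include/NOT-ROI bundle
  selection (`track()`, `select_bundle()`).
* **Landmark profiling** — five landmarks LM1–LM5 warp every streamline to a
  common tract coordinate; diffusion parameters are extracted per
  cross-section and averaged, with segment means such as LM12 (the anterior
  portion) per subject (`project_landmarks()`, `normalize_and_average()`,
  `segment_mean()`).
* **Discrimination statistics** — average-SD Cohen's *d*, pooled two-tailed
  Student's *t* with Bonferroni 0.05/6, tie-corrected ROC/AUC with
  Mann–Whitney significance, Youden cut-offs, covariate-adjusted logistic
  classification (ENTER), exact McNemar on paired classifiers, Pearson
  correlation, and ICC(2,1) reliability (`discrimination_table()`,
  `logistic_enter()`, `mcnemar_exact()`, `icc_absolute_agreement()`, …).
* **Pipeline** — `run_pipeline()` chains all stages under one master seed
  and writes CSV/JSON artifacts plus a manifest; `render_report()` draws the
  group mean ± 1 SE profile plot.

Standard formats are supported throughout: NIfTI + FSL-style bvec/bval,
TrackVis `.trk`, JSON landmarks/ROIs, CSV cohort tables.

## Worked example

Simulate a "patient" phantom whose anterior segment is degraded (FA 0.39
against 0.47 elsewhere, MD 0.81, SNR 20), run the imaging chain, and read
off the anterior (LM12) segment mean:

```r
library(alongtract)

ph <- make_bundle_phantom(phantom_spec(
  fa_inside = c(anterior = 0.39, dorsal = 0.47, posterior = 0.47, ventral = 0.47),
  snr_b0 = 20, seed = 42))
ph
#> C-bundle phantom: 64x64x64 grid, 2 mm voxels, arc radius 36 mm, 1656 tube voxels
#>   segment FA targets: anterior=0.39, dorsal=0.47, posterior=0.47, ventral=0.47; MD 0.81; SNR(b0)=20

maps   <- scalar_maps(fit_tensor(ph$study))
bundle <- track(maps, fa_threshold = 0.2, angle_threshold = 45, step = 1)
sel    <- select_bundle(bundle, list(roi_from_mask(ph$truth$tube_mask, "include", "cingulum")))
proj   <- project_landmarks(sel, ph$truth$landmarks_mm, capture_radius = 10)
prof   <- normalize_and_average(sel, proj, maps, "fa", k_per_segment = 20)
prof
#> Tract profile (fa): 81 positions LM1-LM5, averaged over 1063 streamlines
#>   LM12 segment mean: 0.3973
```

The degraded anterior segment reads 0.397 (generating value 0.39; the small
excess is the Rician FA bias at SNR 20), while the intact dorsal segment at
position 3 reads 0.481. Group-level statistics on a simulated cohort (22
controls vs 14 patients drawn from the reference group distributions):

```r
cohort <- simulate_cohort(cohort_spec(seed = 1))
tab <- discrimination_table(cohort, c("fa_lm12_lh", "md_lm12_lh", "rd_lm12_lh", "vbm_lh"))
tab[, c("parameter", "mean_control", "mean_patient", "cohens_d", "p", "auc")]
#>    parameter mean_control mean_patient cohens_d        p   auc
#> 1 fa_lm12_lh        0.473        0.400     2.00 8.39e-07 0.925
#> 2 md_lm12_lh        0.794        0.929     3.19 7.08e-11 0.990
#> 3 rd_lm12_lh        0.590        0.729     3.12 8.09e-11 0.984
#> 4     vbm_lh        0.548        0.459     1.43 1.40e-04 0.838
```

Each row gives the group means, the average-SD Cohen's *d*, the pooled-*t*
two-tailed p-value and the orientation-corrected AUC: at this simulated
sample size the white-matter parameters separate the groups more strongly
than the cortical density channel, the pattern the along-tract approach is
designed to expose. `run_pipeline(default_run_config(seed = 1), "run/")`
executes the same chain end to end — including per-subject phantoms and
profile extraction — and writes every table, profile and a manifest to the
run directory.

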