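# kinedmd

Ethomic fingerprints and disease-progression biomarkers from full-body
kinematics.

Clinical trials in Duchenne muscular dystrophy (DMD) still lean on
observer- and motivation-dependent functional endpoints (6-minute walk
distance, North Star Ambulatory Assessment, Performance of the Upper
Limb, grip strength). An alternative is to record whole-body movement
during ordinary daily activities with a wearable motion-capture suit
(23 body segments, 22 joints, 60 Hz) and let the data speak: summarise
each recording as a panel of *ethomic fingerprints* — scalar features of
natural movement behaviour — then learn how those features map onto
disease state and its progression. kinedmd implements that analysis as a
tested, reusable R pipeline for methodologists and digital-biomarker
researchers:

- **Fingerprints** — nine feature families (87 features by default):
  workspace volume on a 2-cm voxel grid, hip orbit areas, extremity
  speed statistics, average joint velocities, autocorrelation
  full-widths at half maximum, logistic velocity-distribution scales,
  joint-velocity Pearson correlations, histogram-threshold duty cycles,
  and segment acceleration statistics — plus Kruskal–Wallis group
  screening.
- **Prediction** — Gaussian-process regression (squared-exponential
  kernel + white noise) under nested leave-one-subject-out (LOSO)
  cross-validation with combined forward/backward wrapper feature
  selection: the inner LOSO loop selects features and hyperparameters,
  the outer loop measures pooled RMSE and R², so the held-out subject
  never leaks into any modelling choice. Cross-sectional prediction of
  the clinical scales, T → T+6-month longitudinal prediction (fingerprints
  vs the scale itself as predictor), and nCk learning curves (capped at
  1000 subject combinations).
- **Biomarker** — the monotone progression curve
  `Y(age) = (tanh(X) − tanh(X_min)) / (tanh(X_max) − tanh(X_min))`,
  `X = α·age − β`, anchored at 0 (age 0) and 1 (age 25), with
  α ∈ (0, 0.5], β ∈ [0, 5] and clinical feasibility boxes
  Y(5) ∈ [0.01, 0.15], Y(15) ∈ [0.5, 0.8]. Constrained Bayesian
  optimization (GP surrogate, expected-improvement acquisition) finds
  the feasible curve best predicted from the fingerprints (LOSO error of
  the standardized target).
- **Synthetic cohorts** — patient data of this kind cannot be shared, so
  the package ships a generator producing DMD/control cohorts with the
  documented effect directions (slower extremities, smaller workspace,
  shifted hip/knee angles, lower duty cycle, smaller velocity scale,
  remixed joint couplings, severity-dependent clinical scores with
  ceiling/floor effects), bit-reproducible from a seed. Every stage of
  the pipeline is developed and tested against it.

## Worked example

```r
library(kinedmd)

cfg     <- generator_config(n_dmd = 10L, n_hc = 10L, recording_duration_s = 45)
cohort  <- generate_cohort(cfg, seed = 42)
features <- extract_cohort_fingerprints(cohort$manifest, cohort$recordings)

scr <- kruskal_wallis_screen(features, cohort$manifest$group)
sum(scr$p <= 0.05)
#> [1] 60
```

60 of the 87 fingerprints separate the groups at p ≤ 0.05 on this small
cohort; the strongest are the sagittal hip–knee velocity correlations
(H = 35.3, p = 2.8e-09; DMD median −0.69 vs control −1.00 — the loss of
hip–knee anticorrelation seen in waddling gait) and the extremity speed
variances.

```r
dmd <- cohort$manifest$group == "DMD"
ds  <- as_cohort_dataset(cohort$manifest[dmd, ], features[dmd, ])
cross_sectional_predict(ds, "NSAA")
#> <kine_prediction_report> target=nsaa n=23 subjects=9
#>   RMSE=1.337  R2=0.9347
#>   final subset (2): hiporbit_transverse, logscale_LeftShoulder_Z_deg
```

Nested LOSO prediction of the NSAA from fingerprints: 23 ambulatory
visits of 9 subjects pool to an out-of-fold RMSE of 1.34 NSAA points
(R² = 0.93), using the modal two-feature subset across folds. (These
numbers describe a synthetic cohort — they validate the machinery, not
clinical performance.)

```r
optimize_biomarker(ds, budget = 40, seed = 42)
#> <kine_biomarker_curve> alpha=0.102 beta=1.275 LOSO RMSE=0.1616
#>   Y(5)=0.123  Y(15)=0.646  feasible=TRUE
```

The fitted progression curve respects both clinical boxes; its value and
the per-visit fitted scores are in `$curve` and `$fitted`.

The full pipeline (simulate → fingerprint → screen → predict →
biomarker) is also runnable from the shell via
`Rscript inst/cli/kinedmd.R run-all --seed 1 --out run1`, configured by
a YAML file; see the methods vignette (`vignettes/kinedmd-methods.Rmd`)
for the models, parameters and design decisions.

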