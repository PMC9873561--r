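---
title: "Ethomic fingerprinting and progression biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ethomic fingerprinting and progression biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

kinedmd turns full-body motion-capture recordings of natural, unscripted
behaviour into a panel of scalar movement features ("ethomic fingerprints"),
uses them to predict clinical scales for Duchenne muscular dystrophy (DMD)
under a leakage-safe nested cross-validation protocol, and searches a
constrained family of monotone tanh curves for the disease-progression
biomarker that those features predict best. This vignette explains the
models, the tunable parameters, and the design decisions taken where the
design was genuinely open.

## The data model

Recordings follow the standard inertial motion-capture representation: a
23-segment biomechanical body model with 22 joints, sampled at 60 Hz. Each
joint carries three Euler angles (degrees) in the ISB convention — X
abduction/adduction, Y internal/external rotation, Z flexion/extension —
and each segment a 3-D position (meters). Hinge joints are still
represented with three angles. Two on-disk dialects are read: a CSV dialect
(`time_s`, 66 angle columns, 69 position columns) and an MVNX-subset XML
dialect from which only the joint-angle and position payloads plus the
name declarations are consumed.

Preprocessing is deliberately minimal: a centered moving average with a
21-sample window (~1/3 s at 60 Hz) smooths every channel, and velocities /
accelerations come from central finite differences scaled by the sample
rate (one-sided at the two boundary frames). Edge handling for the moving
average is unstated in the usual description of the technique; we use a
symmetric shrinking window (`min(21, 2k+1)` at distance `k` from an edge)
so that output length equals input length and no phase shift is
introduced. Gaps up to 0.5 s are repaired by linear interpolation at load
time; longer gaps are a hard error — interpolating long stretches would
invent data that the downstream distributional features (logistic scale,
autocorrelation widths) are sensitive to.

## The nine fingerprint families

Under the default configuration the fingerprint vector has 87 named
entries with family sizes 3, 3, 8, 9, 17, 8, 15, 15, 9:

1. **Workspace volume** (cm³; full body, upper body, lower body). Segment
   positions are re-expressed relative to the pelvis, occupancy of a
   half-open 2×2×2 cm voxel grid anchored at the pelvis-frame origin is
   counted — each voxel once, however often it is visited — and multiplied
   by 8 cm³.
2. **Hip orbit area** (cm²; sagittal, coronal, transverse planes). The hip
   position relative to the pelvis is projected onto each anatomical
   plane; occupied 2×2 cm cells × 4 cm².
3. **Extremity velocities** (8): mean and variance of the per-frame
   Euclidean speed of both hands and both feet.
4. **Average joint velocity** (9): mean absolute angular velocity of nine
   major joints' flexion channels.
5. **Autocorrelation FWHM** (17, seconds): the normalised autocorrelation
   of each configured angular-velocity channel is computed to a 10-s lag;
   the full width at half maximum is twice the first sub-sample-interpolated
   crossing of 0.5. Channels that never cross (including constant channels)
   return the cap of 20 s.
6. **Logistic velocity scale** (8, deg/s): maximum-likelihood scale of a
   logistic distribution fitted to each angular-velocity channel,
   initialised at the moment estimate `sqrt(3)·sd/π`. A zero-variance
   channel returns 0 so batch extraction stays total.
7. **Joint velocity correlations** (15): Pearson r of configured channel
   pairs, including the sagittal hip–knee pairs (anticorrelated in typical
   gait) and the coronal hip–hip pair (coupled in waddling gait).
8. **Duty cycle** (15): fraction of time each joint is in motion. The
   motion detector histograms the absolute velocity into 100 equal bins,
   and scans upward from the modal bin for the first bin whose empirical
   probability falls below `p_set` (default 0.005); the left edge of that
   bin is the threshold. The three axis masks of a joint are OR-combined.
   The scan rule is our resolution of an otherwise underspecified "set
   threshold": it isolates the near-zero rest mode whenever the speed
   distribution is bimodal, and returns an all-false mask when it is not.
9. **Segment accelerations** (9): mean/variance of per-frame acceleration
   magnitudes for a configured list of segments.

"Magnitude by root-mean-square" of a 3-vector is read as the per-frame
Euclidean norm; the alternative (norm/√3) differs only by a global
constant per feature and is irrelevant to everything downstream of
standardization. The channel subsets behind the per-channel families are
documented defaults over major limb and trunk joints and are fully
configurable (`family_config()`), since no canonical subset list is
available to ship.

Group screening uses the tie-corrected Kruskal–Wallis one-way ANOVA per
feature (df = 1 for two groups), reporting per-feature p values without
multiplicity correction by default; Benjamini–Hochberg adjustment is
available via `adjust = TRUE`.

## Prediction protocol

Clinical scales (6MWD, NSAA, PUL, MyoGrip percent-predicted) are predicted
from fingerprints with Gaussian-process regression inside a nested
leave-one-subject-out (LOSO) protocol: all visits of a subject form one
fold, the outer loop measures performance, and the inner loop (also LOSO)
drives both wrapper feature selection and hyperparameter choice, so the
held-out subject never influences selection, standardization or tuning.
Cross-sectional 6MWD and NSAA models use ambulatory visits only; PUL and
MyoGrip use all visits.

The GP kernel is squared-exponential with isotropic lengthscale, unit
signal variance and additive white noise, on features and target z-scored
with training-fold statistics. Hyperparameters come from a 5×5 grid —
lengthscale multipliers {0.5, 1, 2, 4, 8} of `sqrt(d)` (the natural
distance scale of d z-scored features) and noise s.d. {0.001, 0.01, 0.05,
0.1, 0.3} on the standardized target — scored by inner-LOSO RMSE. This is
the smallest kernel family compatible with the stated selection rule.

Wrapper selection is floating: forward additions scored by inner-LOSO
RMSE, each followed by conditional backward removals while removal
improves the score, with a subset cap of 10; at least one feature is
always selected and ties resolve to the earliest feature in column
order, making the procedure deterministic. A move must improve the score
by at least 0.01 standardized-RMSE units. This tolerance is deliberately
coarse: accepting noise-level improvements makes every fold run to the
cap with an idiosyncratic subset, which destroys the stability the modal
rule depends on; 0.01 keeps only gains that matter.

The final model uses the modal subset across the per-fold selections.
With 87 correlated features and cohorts of 10–20 subjects, frequencies
routinely tie (often every fold's subset is unique), so ties break by
the per-fold selection score (lowest inner-LOSO RMSE), then toward the
smaller subset, then lexicographically — deterministic, and always one
of the per-fold subsets. A purely lexicographic tie-break was rejected
after it demonstrably picked arbitrary, badly performing subsets in the
all-unique case. Out-of-fold predictions are pooled into the aggregate
RMSE and R² = 1 − SS_res/SS_tot (which may be negative).

One caveat of this published protocol is worth stating plainly: because
the final subset is chosen from *all* folds' selections, folds whose
training data contain a given subject inform the subset later used to
predict that subject. Per-fold selection never sees its own test data,
but the shared modal subset does carry dataset-wide information. At
desk-scale cohorts (30 rows, 87 features) this matters under the null:
targets of pure iid noise pushed through the full protocol show a median
pooled out-of-fold R² near zero, but an upper tail reaching ≈ 0.5 when a
chance-aligned subset wins the modal vote. Permutation-style sanity
checks on such small cohorts should therefore be read against that null
tail, not against zero. The same tail motivates running permutation
checks on control subjects: in disease cohorts all fingerprints share
the severity–age axis, so a subject-level permutation retains genuinely
predictable signal whenever the permuted severities correlate by
chance, which would be misread as leakage.

Two numerical shortcuts matter. First, inner-LOSO scores are computed with
the exact block leave-one-group-out identity from a single Cholesky
factorisation (for fold b, the held-out residual is
`(K⁻¹_bb)⁻¹ (K⁻¹ y)_b`), verified in the test suite against explicit
per-fold refits. Second, during selection the candidate subsets are scored
at fixed median-heuristic hyperparameters (lengthscale `sqrt(d)`, noise
s.d. 0.1); the full grid runs at refit time. Within the inner loop,
feature standardization uses the enclosing training fold's statistics
rather than being recomputed per inner split; the outer loop — the one
every reported metric comes from — standardizes and fits strictly on
outer-training rows, which is what the permutation (anti-leakage) tests
certify.

Longitudinal prediction pairs each visit at time T with the same
subject's visit 6 ± 2 months later (the tolerance accommodates a 6-monthly
visit grid without exact spacing); fingerprints at T predict the scale at
T+6, against the baseline of the scale at T predicting itself, both under
the identical nested protocol. Learning curves evaluate the protocol on
`min(C(n,k), 1000)` seeded subject subsets per cohort size k, enumerating
exhaustively below the cap. Missing clinical scores drop the affected rows
for that target only (no imputation); a target missing for more than 20%
of rows is an error.

## The progression biomarker

The biomarker is the monotone curve
`Y(age) = (tanh(X) − tanh(X_min)) / (tanh(X_max) − tanh(X_min))`,
`X = α·age − β`, `X_min = X(0)`, `X_max = X(25)`, anchored at exactly 0 at
age 0 and 1 at age 25. The box is α ∈ (0, 0.5], β ∈ [0, 5]; α = 0
degenerates the normalisation, so the implemented lower bound is 1e-6.
Clinical feasibility requires Y(5) ∈ [0.01, 0.15] and Y(15) ∈ [0.5, 0.8]
(closed intervals), reflecting the onset window and the
loss-of-ambulation-to-cardiorespiratory window; feasibility depends only
on (α, β) and is evaluated analytically, so infeasible proposals receive
a fixed penalty without touching data.

The search asks: which feasible curve, used as a per-visit target
`y_i = Y(age_i)`, is best predicted from the fingerprints? The objective
is the LOSO GP-regression error with forward-only selection (cap 10) —
cheaper than full floating selection and run hundreds of times inside the
optimizer. Crucially, the error is measured **on the standardized
target** (RMSE/sd(y)). With an absolute-units error the search
degenerates: the flattest feasible curve always wins, simply because its
target spans the smallest range over the observed ages; the
scale-invariant error makes curves with different dynamic ranges
comparable. Optimization is Bayesian: a feasible Latin-hypercube initial
design (10 points), a squared-exponential GP surrogate over standardized
(α, β), and expected-improvement acquisition (ξ = 0.01) over feasible
candidate pools, for a default budget of 100 objective evaluations.

### Identifiability of the fitted curve

A limitation worth being explicit about: when the fingerprints are noisy
functions of an underlying monotone severity s(age), every candidate curve
is (approximately) a monotone reparametrization `h = Y_θ ∘ s⁻¹` of the
same signal, and the prediction error behaves like
`E[h'(s)² σ²] / var(h(s))`. This Rayleigh quotient is not minimized at
`h = id`: it mildly favours curves flattened near the boundary of the
observed severity range. The fitted curve is therefore reproducible and
clinically constrained, but its exact shape inside the feasibility boxes
should be read as "the most predictable monotone summary of the data",
not as an estimate of a unique ground-truth curve. The package's recovery
experiments on synthetic cohorts quantify this: the returned curve always
respects both clinical boxes, while its pointwise deviation from the
generating curve can reach ~0.2 at intermediate ages.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes. DMD subjects
(default 15; baseline ages 5–16, visits at 0/6/12 months) carry a
severity equal to the tanh curve at (α, β) = (0.15, 1.8) — a feasible
point of both clinical boxes — while controls (default 15; ages 4–16,
visits at 0/12 months) have severity 0.

Each recording is a sum of gated sinusoid oscillations: per-channel
oscillators (2 components, 0.3–0.9 Hz) are switched by a two-state
activity-bout gate (2-s blocks, healthy duty 0.55), on joint-specific
baseline angles, with additive logistic-distributed velocity noise
(scale 2 deg/s at severity 0) leak-integrated into the angles and mostly
gated so rest periods are genuinely quiet. Severity: attenuates
oscillation amplitude (60% at severity 1) and frequency (30%), lowers the
gate duty (−0.35), shifts the hip flexion baseline (+15°) and the knee
baseline (−10°), shrinks the velocity-noise scale (−50%), weakens the
sagittal hip–knee anticorrelation (−70%) and strengthens coronal hip–hip
coupling (+0.6). Non-ambulant severities (≥ 0.55) attenuate — never
zero — lower-body channels (×0.25) so upper-body features stay
informative. All random draws precede any severity-dependent scaling, so
the same seed yields coupled noise streams across severities, and every
subject-visit uses named substreams (kinematics vs scores) of the cohort
seed, making cohorts bit-reproducible.

Clinical scores decrease with severity in expectation with Gaussian noise
and the scales' ceiling/floor effects: NSAA = 17 activities × grades 0–2
(integer 0–34, s.d. 1.5), 6MWD up to 520 m (s.d. 25 m; 0 when
non-ambulant), PUL 2.0 on its 22-item 0–42 total (s.d. 1.5; the 42-point
maximum is this generator's convention for the published item set), and
MyoGrip as percent predicted (s.d. 5).

Effect directions and significance — not absolute values — are the
calibration target: generated cohorts reproduce lower speeds, smaller
workspaces, lower duty cycles, smaller logistic scales and higher
autocorrelation FWHM in the DMD group, with Kruskal–Wallis separation at
n = 15/group. What the generator does **not** emulate: biomechanically
realistic gait, activity composition (meals vs play), sensor artefacts,
or any real cohort's absolute clinical-scale distributions. Tests passing
on synthetic cohorts therefore certify the pipeline's statistical
machinery (no leakage, correct arithmetic, right effect directions), not
clinical performance on real patients.

## Problem sizes and numerical choices

The test and acceptance workloads use 45–120 s recordings (the
generator default of 120 s for the longitudinal comparisons, where
fingerprint precision drives the result; 45 s where the check is
structural), cohorts of 8–20 subjects per group, optimizer budgets of
25–100 evaluations and the nCk learning-curve cap of 1000 — sizes chosen
so the full suite exercises every stage end-to-end on a single CPU while
remaining statistically meaningful (e.g. ≥ 1000 samples for the logistic
fits, ≥ 2× the 10-s autocorrelation horizon per recording). Other numerical choices: Cholesky
jitter escalation (1e-10 upward by decades, then error) for degenerate
kernels; correlations of zero-variance channels report 0; duty-cycle
detection on a constant channel reports an all-false mask; the biomarker
penalty constant is 10 (far above any realistic standardized RMSE).

## Command-line use

The analysis stages map to subcommands of a thin Rscript front-end
(`inst/cli/kinedmd.R`): `simulate`, `fingerprint`, `screen`,
`predict-cross`, `predict-longitudinal`, `fit-biomarker`, `run-all`, with
a YAML configuration file (`--config`) and `--seed`, `--out`, `--target`,
`--horizon-months`, `--budget` overrides. Every stage writes CSV/JSON
reports embedding the configuration hash and seed, so re-running a stage
from stored intermediates reproduces its report exactly.
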