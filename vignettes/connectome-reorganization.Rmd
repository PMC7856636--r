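---
title: "Hub disruption and modular reorganization in functional connectomes: methods"
author: "hubshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub disruption and modular reorganization in functional connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hubshift` implements a complete resting-state functional-connectome group
analysis for chronic-pain-style cohorts, starting from extracted ROI
time-series (voxel-level preprocessing is out of scope). The pipeline is:

1. **Preprocessing** — discard initial saturation volumes; regress out an
   intercept, six rigid-body motion parameters and the global / white-matter
   / CSF signals; composite motion censoring (FD > 0.5 mm OR |DVARS z| > 2.3
   OR |intensity z| > 2.3, each hit scrubbed together with its two
   neighbours on either side); zero-phase second-order Butterworth band-pass
   0.008–0.1 Hz.
2. **Quality control** — subjects with fewer than 200 usable volumes are
   excluded (inclusive boundary: exactly 200 passes), as are within-group
   connectivity outliers (mean between-subject correlation of vectorised
   connectivity more than 2 SD below the group mean).
3. **Graphs** — full signed Pearson correlation matrices over usable volumes;
   binary undirected graphs at link densities 2–10% (exactly
   `round(d N(N-1)/2)` strongest signed edges; deterministic tie-break by
   value then lexicographic node pair).
4. **Topology** — nodal degree, clustering, efficiency (1/∞ = 0 for
   unreachable pairs), unnormalised geodesic betweenness; global values are
   node means; Louvain modularity averaged over repetitions; small-worldness
   `(CC/CC_rand)/(E_rand/E)` against Maslov–Sneppen degree-preserving
   rewirings, criterion > 2.
5. **Hub disruption** — per subject and metric, the slope K of
   `(subject − control mean)` on `control mean` across nodes; ANCOVA group
   contrasts (age + sex), FDR-screened partial clinical correlations, and a
   node-subsampling robustness analysis (20% of nodes kept, 100 draws).
6. **Nodal statistics** — mean degree-difference profile with a ±2 SD flag
   and a two-sided group-label permutation p per node; stepwise (enter .05 /
   remove .10) clinical models on flagged nodes; elastic-net (α = .5)
   prediction of pain intensity from all age/sex-adjusted nodal degrees, λ
   chosen by 10-fold CV on a 100-point grid, frozen and validated on
   hold-out patients.
7. **Modular reorganization** — categorical multislice modularity (subjects
   as slices, ω = 0.1, γ = 1.5, 10% density) via a generalized Louvain;
   agreement matrices averaged over subject subsamples; patient-minus-control
   agreement difference; per-node reorganization scores with a one-sided
   group-label permutation null at p < .01.

# Interfaces and conventions

Every stage is an exported function over S4 containers
(`RoiTimeSeriesSet`, `ConnectomeSet`, `BinaryGraphStack`) with subject
metadata in an `S4Vectors::DataFrame`; `runPipeline()` chains them from a
single config list, writes one CSV per result surface plus a hashed
manifest, and `pipelineReport()` assembles a text report. Identical configs
give byte-identical outputs: every stochastic stage derives its stream from
the master seed and a stage tag.

Decisions taken where the procedure was genuinely open:

- **Thresholding ranks signed correlations** (not absolute values), the
  dominant convention for sparse Pearson connectomes; `edge ranking` is a
  fixed choice here, not a config switch, because every downstream
  calibration depends on it.
- **Band-pass and censoring order**: censoring marks volumes first; the
  filter runs over the full regressed series with censored volumes linearly
  interpolated (avoiding spectral leakage from spike gaps), and the mask is
  re-applied before correlation. A lone high-pass step would annihilate the
  band of interest, so only the band-pass is applied.
- **Control normative vector**: every subject, including each control, is
  referenced to the full control-group mean (`looControls = TRUE` switches
  controls to leave-one-out; the default slightly biases control K toward 0,
  which cancels in group contrasts).
- **Group-level K** is reported both as the fit to the group-mean difference
  profile (`K_pooled`) and as the mean of subject-level slopes
  (`K_mean_of_subjects`); for complete data the two coincide.
- **Repeated-measures contrast across densities** is implemented as OLS on
  the subject × density long table with cluster-robust (by subject)
  standard errors.
- **Elastic-net convention**: penalty `λ(α‖β‖₁ + (1−α)/2‖β‖₂²)` on
  internally standardised predictors (1/n variance), coefficients reported
  on the original scale; the λ grid spans four decades below the smallest
  all-zero λ. The solver is glmnet; the package checks the KKT subgradient
  conditions of the returned solution at the chosen λ rather than trusting
  convergence blindly.
- **Permutation sidedness**: nodal degree differences use two-sided p on
  |Δ|; modular reorganization uses one-sided p (only excess reorganization
  is evidence), matching the respective estimands.
- **Agreement within one categorical run** is the fraction of slices in
  which two nodes share a community; the run-level agreement is averaged
  over subsample repetitions. The inner repetition count is reduced by
  default (desk scale) and configurable up to the full cluster-scale
  setting; Monte-Carlo error of the AM estimator shrinks as 1/√reps and is
  below 0.02 RMS for the defaults used in the tests.

# The synthetic cohort generator

No cohort data ship with the package; a fully parameterised generator plants
every effect the pipeline is designed to detect, so each stage has a
recovery test. `cohortDesign()` holds the ground truth; `generateCohort()`
is byte-deterministic given the design.

**Signal model.** Region signals are a linear factor model over unit-variance
AR(1) sources band-limited to 0.008–0.1 Hz: one factor per module, a set of
long-range pair factors, and one local ring-window factor per region, plus
independent region noise and weak white-matter/CSF leakage. Loadings:

- each region loads on its own module (uniform 0.5–1.3) and at 40% of that
  on the cyclically next module;
- each region shares a ring-window factor (0.55 of own loading) with the
  next two regions of its module ring — the local backbone that gives every
  node clustered neighbours, as spatial adjacency does in real parcellations;
- roughly one region in five forms a long-range pair with a region in a
  distant module (1.2 × own loading on a private factor), emulating strong
  homotopic couplings; these provide the shortcut edges that make the sparse
  graphs small-world;
- module sizes decrease linearly (about 4:1 largest to smallest);
- region noise SDs are heterogeneous (uniform 0.7–1.3): a region's noise
  level scales all of its correlations, so low-noise regions are
  high-degree. Four hub regions per module combine boosted own loadings,
  the low-noise end, and bridges into two further modules, producing a
  heavy-tailed degree profile.

These structural constants were fixed once, against the operating
characteristics the cohort is meant to exhibit (small-world control graphs
at 5% density, Louvain modularity ≈ 0.7, a normative degree profile whose
spread dominates finite-scan degree noise), and are not exposed as user
knobs.

**Planted effects.**

- *Hub disruption*: patient loadings are scaled by `1 + g·kTrue·z_i`, with
  `z_i` the standardised control expected degree (computed analytically from
  the loading covariance). The perturbation is attenuated twice on its way
  to the estimand — correlations only partially track loading scale, and
  thresholded degree only partially tracks correlation scale — so the
  internal gain `g` was calibrated once so that the recovered group K_D
  equals `kTrue` on the default design (recovered −0.20 ± 0.01 at
  `kTrue = −0.2`, n = 40/40, 5 seeds). `kTrue = 0` disables the mechanism.
- *Module switching*: designated non-hub regions (one per module by default)
  have their module factor and their ring ties reassigned to a target
  module in patients, so their community identity genuinely moves.
- *Pain mapping*: a sparse 4-region weight map β (one non-hub region in
  each of four modules, graded ±2 weights) over expected nodal degree
  generates NRS = 6.5 + 1.3·standardised(β'degree) + N(0, 0.6), clamped to
  [0, 10]. "Expected nodal degree" here is the expected degree of the
  *realized* thresholded graph — a probit-smoothed count of correlations
  above the subject's density threshold, computed after projecting the
  global-signal direction out of the loadings (nuisance regression removes
  it from the data, and hard-threshold analytic degree tracks realized
  degree poorly otherwise). Between-subject variation on the pain regions
  is encoded as a log-normal (SD 1.0) multiplier on their noise levels,
  patients only: a region's noise level is the effective per-subject lever
  on its degree, and pain-encoding variability is a patient-state
  phenomenon — keeping controls at the structural noise profile keeps the
  normative degree profile clean (less regression dilution in K). All
  subjects additionally carry baseline loading jitter (SD 0.12).
- *Motion*: each volume is corrupted with probability `motionRate` (default
  0.03); corrupted volumes receive a global signal spike and FD drawn
  uniform(0.6, 1.5) mm, so the FD > 0.5 mm rule provably fires; clean
  volumes are clamped below all three censoring thresholds so a
  `motionRate = 0` cohort censors nothing.
- *Covariates*: age (patients ≈ 65 ± 7, controls ≈ 60 ± 8), sex, and a
  questionnaire battery with realistic means/SDs; an optional `ageEffect`
  mode couples age to loadings to exercise covariate adjustment.

**What the generator does not emulate** (so what passing tests do not show):
haemodynamics and scanner physics; spatial autocorrelation beyond the ring
backbone; non-stationary dynamics; real atlas geometry (no MNI coordinates);
site/scanner batch effects; and any specific empirical region assignment —
recovery results validate the machinery, not anatomical claims.

# Numerical choices

- Degree-difference regressions use the exact closed form; K is undefined
  (error) for a zero-variance normative profile.
- The multislice optimizer is a generalized Louvain in C++: greedy
  single-vertex moves over (node, slice) vertices with the categorical
  coupling term, then community aggregation on a dense quality matrix,
  iterated to no gain; deterministic Fisher–Yates shuffles from a seeded
  mt19937. Quality is reported unnormalised; dividing a single slice's value
  by 2m gives Newman–Girvan modularity, which is how the reduction to
  single-graph Louvain is tested.
- Permutation p-values use the add-one estimator `(1 + #exceed)/(1 + n)`,
  so the floor is `1/(1 + n)` and `n ≥ 99` is required to resolve p < .01.
- The elastic-net grid descends four decades from λ_max; CV folds are a
  seeded random partition; `thresh = 1e-12` so the KKT check at 1e-6 is
  meaningful.
- Problem sizes in the test-suite recovery studies are reduced relative to
  the full design (e.g. 64-region cohorts, inner agreement repetitions 2–3,
  99–500 permutations), chosen as the smallest sizes at which the planted
  effects are comfortably detectable; the full-scale settings remain the
  function defaults.

# Known limitations

- The K calibration gain is specific to the default analysis density (5%)
  and the default structural constants; designs far from the defaults will
  recover a proportionally scaled slope.
- Degree-difference regression against a noisy normative mean carries an
  intrinsic regression-dilution bias of order
  −var(degree noise)/(n_controls · var(normative profile)); with the default
  design this is ≈ −0.01 to −0.02 and is visible in null cohorts.
- The agreement-matrix estimator is Monte-Carlo; at the desk-scale defaults
  its RMS error is ~0.02, which bounds how small a planted reorganization
  can be and still be detected.
- `qcConnectivityOutlier` needs at least 3 subjects per group and skips
  smaller groups with a warning.
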