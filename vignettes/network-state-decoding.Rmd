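---
title: "Decoding task-evoked network states: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding task-evoked network states: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The scientific question

When a person performs different cognitive tasks, the brain does not merely
activate different regions: it transiently reconfigures the *correlation
structure* among regions — its dynamic network state. `netstate` implements
a complete analysis chain for studying this phenomenon with block-design
fMRI: decode which of twelve tasks a one-minute block of data comes from,
ask whether tasks that are close in behavioural-psychometric space evoke
similar network states, and ask whether people who express these states
more distinctly also perform better on the tasks.

Because raw multi-subject fMRI is large and slow to obtain, the package
ships a synthetic-cohort generator that plants all of the structure the
downstream analyses are designed to recover. Every stage of the pipeline is
therefore exercisable, with known ground truth, on a laptop.

# The generative model

A cohort is defined by a `sim_config()`: by default 60 subjects perform 12
tasks, each task acquired as one run of three 1-minute blocks, each
preceded by 20 s of rest, sampled at TR = 2 s (120 frames per run). ROI
time series for subject $s$ during condition $c$ are drawn as a stationary
AR(1) process whose innovation covariance is the condition correlation
matrix:

$$x_t = \rho\, x_{t-1} + \sqrt{1-\rho^2}\; \varepsilon_t,
  \qquad \varepsilon_t \sim \mathcal N(0, R_c),$$

with $\rho = 0.3$ mimicking BOLD temporal autocorrelation. At rest,
$R_c$ is a baseline correlation with stronger within-network coupling
(0.35 within, 0.05 between, for 7 networks labelled DM, DA, FP, LI, SM,
VA, VS). During task $t$ the baseline is perturbed in Fisher-z space:

$$R_{s,t} = \tanh\!\big(\operatorname{atanh}(R_\text{rest})
  + \phi_s\, \Delta z_t\big),$$

where $\phi_s \in [0,1]$ is the subject's *fidelity* — how strongly they
express the task state — and $\Delta z_t$ is the planted task
perturbation. Task activation enters as a canonical double-gamma HRF
convolved boxcar scaled by $\phi_s$ times a task-specific ROI amplitude
vector, plus white measurement noise (SD 0.3 against unit-variance
intrinsic fluctuations). Behavioural scores are affine in fidelity,
$\text{score}_{st} = \phi_s + \varepsilon$, $\varepsilon \sim
\mathcal N(0, 0.15)$, so the first principal component of the score table
can recover $\phi$ — the only property the individual-differences claims
require of the behaviour model.

## Structure of the planted task states

Each task's perturbation decomposes into three components with
configurable mixing weights:

* a **shared** component on within-network edges, common to all tasks
  (per-edge magnitude 0.25 Fisher-z);
* a **factor prototype** shared by the tasks loading on the same
  psychometric factor (magnitude 0.30); three orthogonal factors (VS, RE,
  VR) each dominate four tasks, with factor loadings built so that
  within-factor tasks are strictly closer in loading space than
  cross-factor pairs;
* a **task-unique** component (magnitude 0.40) placed predominantly on
  *between*-network edges (probability 0.8 by default; at 1.0 the
  constraint is hard).

A deliberate geometric choice makes the construction robust: every
component is a random *matching* — an endpoint-disjoint edge set — and the
three components draw from three vertex-disjoint ROI pools. The total
perturbation of any task is then itself a matching, whose symmetric matrix
has eigenvalues $\pm\delta$ per edge. As long as the largest per-edge
magnitude stays below the smallest eigenvalue of the baseline correlation
(about 0.65 here), every condition correlation is positive definite *by
construction*, for any seed and any ROI count. Positive definiteness is
nevertheless verified explicitly at construction and generation aborts
with a report if a requested scale breaks it.

The default magnitudes were chosen once so that, at the package's standard
test scale, twelve-way decoding lands comfortably between chance (8.3%)
and ceiling, with connectivity carrying at least as much class information
as activation and the two being complementary — the qualitative regime the
analyses are designed for. They are not calibrated to reproduce any
particular real-data accuracy.

## What the generator does not emulate

No head motion, physiological noise, scanner drift, slice timing, spatial
autocorrelation of voxel noise, or haemodynamic variability across regions
and subjects. Synthetic data enters the pipeline "preprocessed". Passing
tests therefore demonstrate correctness of the estimators and protocols
under the stated model, not robustness to real-world artefacts.

# Activation mapping

Per run, a block-design GLM uses one HRF-convolved unit-height boxcar per
block, so the per-block activation estimate is a single OLS coefficient in
the input signal's units (the HRF kernel is normalised to unit sum, making
a long block's regressor plateau at 1). Group maps are one-sample t-tests
across subjects (activation is defined as positive t), thresholded by
Benjamini–Hochberg FDR at the voxel level. The minimal-cluster rule forms
clusters on a relaxed uncorrected threshold (p < 0.01) under 26-neighbour
connectivity, compares observed cluster sizes to a sign-flip permutation
null (the procedure choice is recorded in `threshold_meta`; the cluster
p-value recipe is otherwise underdetermined), applies BH across clusters
at 0.05, and keeps FDR-surviving voxels inside clusters at least as large
as the smallest surviving cluster. In the no-threshold limit (`alpha = 1`,
`relaxed_p = 1`) the mask is exactly the positive-t voxels and no cluster
stage runs.

Conjunction analysis is conservative intersection: the AND of the task
masks carrying the minimum statistic, plus union, per-voxel overlap
counts, and exact-k percentages over the union.

# Watershed parcellation

Suprathreshold statistic volumes are segmented by ordered flooding:
voxels are visited in decreasing statistic order; a voxel with no labelled
neighbour seeds a new region (it is a local maximum among processed
voxels), otherwise it joins the labelled neighbour with the highest
statistic. Two numerical choices matter and are fixed for determinism:
plateau ties are broken by ascending linear voxel index, and label ties by
the lowest label. Regions smaller than `min_size` (default 10 voxels) are
merged into the neighbouring region with the highest shared-boundary
statistic, or discarded when isolated. Defaults: 26-connectivity, no
pre-smoothing (input maps are already smooth); both exposed as arguments
since no canonical values exist for them.

# Task similarity

Psychometric similarity is the radial basis function kernel
$S = \exp(-\mathrm{pD}^2)$ of the Euclidean distance between task rows of
the factor-loading matrix; activation-pattern similarity is the Pearson
correlation of task mean-activation vectors (with the eigen-spectrum of
the similarity matrix attached as a scree); spatial overlap is Dice,
$2\,\mathrm{TP}/(2\,\mathrm{TP}+\mathrm{FN}+\mathrm{FP})$, defined as 0
for two empty masks. Association between two similarity structures is the
one-tailed Pearson correlation of the vectorised strict upper triangles
(66 pairs for 12 tasks), with p-values from the t transform of r and BH
correction across whatever family of tests a figure declares. A Mantel
permutation test is deliberately not used — plain correlation on
vectorised pairs is the protocol the analyses specify — so p-values
inherit the usual caveat that pair entries are not independent.
Hierarchical clustering attached to similarity matrices uses average
linkage on $1-S$ (no linkage is canonical; average is the least committal).

# Dynamic functional connectivity

The mean task-evoked response is removed by finite-impulse-response
regression: one indicator regressor per post-onset lag (default: block
frames + 8, covering the HRF tail at TR 2 s), shared across a task's
blocks, fitted by OLS per ROI. This absorbs *any* response shape repeated
across blocks — the property that matters, since co-activation masquerades
as connectivity if left in. Frames are labelled task/rest with a 2-frame
(≈4 s) haemodynamic shift, and 2 settling frames after every transition
are discarded; both are configurable.

Per block event, connectivity is the Pearson correlation of residual task
frames, Fisher z-transformed; the pooled rest frames of the same run give
the baseline; the dFC feature is the difference $z_\text{task} -
z_\text{rest}$ per ROI pair. Fisher z is applied before differencing so
the contrast is additive on a variance-stabilised scale. A 7-network
labelling reduces the $K(K-1)/2$ edges to 28 features (7 within-network
plus 21 between-network-pair means), each edge contributing to exactly
one feature; subject-level reduced connectomes average a subject's 36
events.

# Classification machinery

The multi-class problem is reduced by error-correcting output codes over
binary linear SVMs — 12 learners for one-vs-all, 66 for one-vs-one —
with fixed default regularisation (C = 1), features z-scored on training
statistics, and *no* hyperparameter tuning anywhere; decoding minimises
the code-weighted mean hinge loss, ties to the lowest class index. The
SVM backend's decision-value sign is not guaranteed by its API, so each
learner stores an orientation calibrated on its training data.

The performance protocol splits *subjects* (never events) into 75%
training / 25% test, fits a true model and a null model whose training
labels are scrambled within subject (preserving each subject's class
balance — the least destructive reading of label scrambling), scores
held-out F1-macro, and repeats 100 times. Significance is the empirical
probability $p = (b+1)/(m+1)$ with $b$ the number of null repetitions
beating the mean true score. An internal 5-fold CV inside each training
set splits *events* rather than subjects: the resulting subject leakage
is deliberate, as it is exactly what makes within-sample CV estimates
optimistic relative to the subject-level held-out score, and quantifying
that optimism is the estimate's purpose.

Stacking is two-stage: per metric, an internal 5-fold CV over training
subjects produces out-of-fold signed one-vs-all decision values (the
positive binary scores, PBS; 12 per metric, 24 stage-2 features for two
metrics); a stage-2 ECOC model is trained on these; at test, each of the
five stage-1 fold models scores the test events and the majority vote of
the five stage-2 predictions is the label (ties to the lowest class).

Sparse connection selection swaps the binary learners for L1-regularised
logistic regressions in a leave-one-subject-out loop; positive and
negative nonzero weights are binarised separately, averaged across tasks
and then models, and the top set is the edges above the 99.9th percentile
of each frequency map. No penalty strength is canonical, so each model
uses the smallest penalty retaining at most 5% nonzero weights, recorded
in the output.

# Individual differences

The behavioural performance index is the first unrotated principal
component of the column-standardised subject × task score table, with the
sign fixed so the mean task loading is non-negative, standardised to zero
mean and unit variance. Per-subject classifiability counts correctly
classified blocks out of 36 (majority prediction per event when the
repeated protocol predicts an event several times); subjects below chance
+ 2/36, or more than 3 SD below the cohort mean, are flagged as outliers
— the flagging rule is made explicit here because only "very low
accuracy" exclusion is canonical. The association with the performance
index is a right-tailed Pearson test, BH-corrected across the declared
model family.

The connectome predictor is least-squares gradient boosting over the 28
network features, learning rate 1 (the conventional least-squares
boosting default), with trees limited by their number of branch-node
splits. One structure (max splits, number of trees) is selected by an
outer leave-one-subject-out grid search over {1,2,3,5} × {3,5,10,25} —
bracketing the small structures such data support — scored by LOO mean
squared error, with ties going to the simpler structure; all LOO folds
share that single selected structure (re-selecting per fold would leak
the fold's target into structure choice and was rejected). A full-sample
ensemble is additionally fitted only for split-gain importance
inspection.

# Problem sizes and numerical tolerances

The package's own test and acceptance runs use cohorts of 24 subjects,
with 40 ROIs for protocol calibration (the null-model chance check) and
20 ROIs for the repeated-classification recoveries — sizes at which all
planted effects are comfortably recoverable while the full suite runs in
minutes on one CPU. Planted-edge dFC recovery is verified at 10-minute
noise-free blocks against a 0.05 Fisher-z tolerance; correlations are
clamped at $|r| = 1 - 10^{-7}$ before the z-transform; GLM fits refuse
rank-deficient designs rather than silently pivoting; cluster-size nulls
default to 200 sign-flip permutations.

# Known limitations

* The cluster-correction null (sign flips of subject maps) assumes
  symmetric subject-level errors; heavy-tailed group effects would need a
  different null.
* Watershed behaviour on large plateaus is deterministic but arbitrary
  within the tie-break rule.
* The stack protocol's majority vote over five fold models can lose a
  little accuracy when one metric vastly dominates; its advantage shows
  when metrics are comparably informative and complementary.
* Pairwise-similarity association p-values treat task pairs as
  exchangeable units, as the protocol prescribes; they are not Mantel
  tests.
* Boosted-tree importance is split-gain based and, like all such
  measures, favours features with more candidate splits when features are
  correlated.
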