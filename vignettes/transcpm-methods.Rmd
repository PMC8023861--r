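---
title: "Methods: transdiagnostic ridge CPM of latent memory phenotypes"
author: "transcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transdiagnostic ridge CPM of latent memory phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(transcpm)
```

This vignette is the package's account of its own science: the model it
fits, the assumptions behind it, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical and design choices made where the problem left them open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The modeling problem

The pipeline asks two complementary questions of a multi-task functional
connectome cohort spanning several diagnostic groups:

1. Can a *single* model, trained irrespective of diagnosis, predict a
   memory phenotype in held-out subjects — including subjects from a
   diagnostic group the model never saw?
2. Do the diagnostic groups differ in whole-brain connectivity at all, and
   if so, is that difference pattern the same circuitry the predictive
   model uses, or distinct from it?

The first is answered with ridge-regularized connectome-based predictive
modeling (rCPM) under 10-fold, leave-one-group-out, and cross-dataset
validation; the second with an edgewise mass-multivariate analysis (MANOVA
across task connectomes) and overlap statistics between the two maps.

## Data model and assumptions

A cohort is a `task_connectome_set` (subjects × tasks × edges, Fisher-z
units; edges are the strict upper triangle of the symmetric node × node
matrix in row-major order) paired with a `phenotype_table` (diagnostic
group, motion summaries in mm, raw behavioral measures). The method assumes:

- connectivity is summarized per edge by the Fisher z of a Pearson
  correlation, so each edge is approximately normal with stabilized
  variance;
- a latent behavioral construct, not any single instrument, is the
  prediction target; instruments load linearly on it with independent
  noise, which justifies summarizing them by a first principal component;
- edge–phenotype association is approximately linear, so correlation
  screening plus a linear ridge model is well specified;
- head motion may confound both edges and behavior, and its linear
  component is removable by partial correlation at the selection step.

## Pipeline stages and their parameters

**Motion QC** (`motion_qc`): excludes subjects with grand-mean
frame-to-frame displacement strictly above 0.15 mm across tasks, or above
0.20 mm on any single task. Comparisons are strict (a subject exactly at a
limit is kept) and subjects with missing motion are excluded rather than
imputed — a conservative choice that can only lose data, never fabricate
it.

**Connectome construction** (`compute_fc`, `general_fc`): Pearson
correlation of node time courses, `|r|` clipped at `1 - 1e-7` before
`atanh` so duplicated or perfectly coupled nodes stay finite; zero-variance
nodes have their edges zeroed and are flagged rather than erroring, since a
flat regressor carries no information. Task-evoked structure is *not*
removed: connectomes are built from the raw task time courses. General
functional connectivity z-scores each run per node before concatenation so
runs with different scales contribute equally.

**Latent phenotype** (`fit_latent` / `apply_latent`): measures are z-scored
by *training* mean and sd, and the first principal component is retained —
one construct score per subject. PCA is computed on the correlation scale
(z-scored measures) because instruments are on arbitrary scales; this is
configurable in principle but fixed here. The loading sign is set so the
loading sum is non-negative (higher score = better performance for
positively scored instruments); PCA leaves the sign undefined and any fixed
convention works, but this one keeps signs interpretable. The API only ever
fits on training rows; test subjects are scored with stored training
statistics, so no test information can leak into the construct definition.

**Edge selection** (`select_edges`): per task and edge, Pearson correlation
with the phenotype; with motion supplied, the partial correlation given
motion (identical to correlating motion-residualized edge and phenotype),
with df = n − 3. The p-value is the two-sided t transform
`t = r sqrt(df/(1 - r^2))`; edges with p < α = 0.01 are selected, both
signs pooled. Two-sided is the coherent choice when both positively and
negatively correlated edges are kept. Zero-variance edges are silently
never selected.

**Ridge fit** (`rcpm`): selected features from all tasks are z-scored by
training statistics and enter one ridge regression with unpenalized
intercept (equal to the training phenotype mean, since features are
centered). The penalty λ is chosen by inner 5-fold cross-validation
minimizing MSE over a 13-point log-spaced grid `1e-3 … 1e3`; the grid and
fold count are configurable and a fixed λ can be supplied for speed or for
λ-sweep analyses. The solver uses the kernel (dual) form
`β = Xᵀ(XXᵀ + λI)⁻¹y` when features outnumber subjects — exactly the
penalized normal-equation solution, verified in tests to 1e-8 against the
direct solve. If selection returns no edges the model is flagged empty and
predicts the training mean; k-fold records such folds in a failure report
instead of aborting.

**10-fold CV** (`kfold_cv`): the whole sample is divided irrespective of
group into 10 folds (sizes differing by at most 1), and the *entire*
pipeline — construct PCA, selection, ridge — is refit inside each training
fold. Predictions are pooled across the 10 folds to give one
`q² = 1 − SSres/SStot` per division; the median over divisions is the
headline statistic. The study-scale default is 1000 divisions; desk-scale
analyses in this package's tests use 20–50, which is enough for a stable
median at the simulated effect sizes. Negative q² is reported as-is with
the root flagged undefined rather than clamped, preserving information
about how badly a model extrapolates.

**Permutation null** (`permutation_test_behavior`): the behavior-connectome
correspondence is shuffled (motion stays with the connectomes, being an
imaging-derived quantity) and the full CV analysis is rerun per shuffle;
`p = (#{null > observed} + 1)/(n_perm + 1)`, one-tailed. The comparison
statistic is the median per-division q² rather than its square root: the
root is undefined whenever q² < 0, which is the typical null outcome, while
q² orders identically wherever both exist.

**Leave-one-group-out** (`leave_group_out`, `group_permutation_test`): one
split per diagnostic group (the possibilities are exhausted; no
iteration), scored by Pearson r between actual and predicted. To ask
whether diagnosis itself carries information, group labels are permuted
(200 times by default) preserving group sizes; observed performance above
the null's 97.5th percentile means the true label assignment was
*detracting* information, below the 2.5th *contributing*, otherwise the
label is uninformative. An empirical two-sided permutation p per group is
FDR-corrected at q = 0.001 across groups and a group is only classified
away from "uninformative" when FDR-significant; the percentile phrasing in
the literature is compressed, so the direction of the mapping is
implemented as stated and the conservative FDR gate guards against reading
noise as signal. A constant prediction (an empty model's fallback) has
undefined r and is reported as 0.

**Selection consistency** (`consistency_degree`): an edge is consistent if
selected, in any task, in at least 95% of divisions; the per-node degree of
consistent edges summarizes model anatomy and always sums to twice the
consistent-edge count.

**External validation** (`external_validate`): each dataset independently
gets a "general memory" construct (PCA over all its memory measures, all
subjects — the datasets' instruments need not match), connectomes are
reduced to a single general-FC matrix per subject, the model is trained on
every subject of one dataset and applied to the other, in both directions.

**Edgewise MANOVA** (`edgewise_manova`, `pairwise_contrast`,
`mma_summaries`): per edge, the m-task response vector is tested against
the group factor using Wilks' Λ with Rao's F approximation (Pillai's trace
available); with one task this reduces exactly to the one-way ANOVA F.
Pairwise contrasts use two-sample Hotelling's T² with the exact F
transform. Edges with singular within-group or total SSCP are flagged and
reported at p = 1 rather than dropped, keeping the edge indexing intact.
Significance is Benjamini–Hochberg FDR at q = 0.05 across all tested
edges; node scores sum the F statistic over significant incident edges and
network scores sum it by endpoint network pair. MANOVA is used for the
4-group omnibus and Hotelling's T² for pairwise contrasts.

**Interpretation** (`node_contribution`, `task_contribution`,
`network_average`, `profile_similarity`, `hypergeometric_overlap`,
`edge_set_network_profile`): node contributions
`W_n = Σ_{k incident to n} Σ_m B(k,m) β_mᵏ std(E_k(:,m))` are signed by
default (the formula has no absolute value; cancellation is informative),
with a magnitude option for display; the outer sum runs over the edges
incident to the node, the only reading consistent with "summed across all
tasks and edges". Task contributions use magnitudes `|β| std` before
normalizing to sum 1, so "contribution proportion" is non-negative; a
signed variant exists behind a flag. Network overlap uses the
hypergeometric upper tail `P(X > x)` computed by `stats::phyper` (log-gamma
based, numerically stable), and the per-cell "likelihood" `1 − p` used for
stacked profiles is a labeled reporting convenience, not an inferential
quantity. Map comparisons default to unthresholded contribution vectors.

## The synthetic cohort generator

`simulate_cohort` draws, per subject: a standard-normal latent trait `m`;
behavioral measures `x_j = λ_j m + ε_j`; motion as `|N(0.08, 0.03)| mm`
(per-task jitter sd 0.02 mm) with trait correlation 0.2 induced through a
Gaussian copula; and edges

```
e_km = μ_k + b · profile_m · m · 1[k ∈ signal]
           + δ_g · 1[k ∈ group set] + c · motion · 1[k ∈ motion set] + noise
```

with `μ_k ~ N(0.3, 0.25)` (plausible Fisher-z baselines) and noise sd 1.
Defaults are the cohort conditions this package targets: 172 subjects in
groups 75/30/35/32; 268 nodes; 6 tasks; 150 signal edges with
`b = 0.3735`, giving a planted edge–trait correlation
`b/sqrt(b² + 1) = 0.35`, concentrated on the first task so task
attribution is testable; 50 group-difference edges, disjoint from the
signal edges so that "the predictive network and the group-difference
network are distinct" is a testable ground truth, with deltas
(0, 1, −1, 0.5) edge-units for HC/SCZ/BPAD/ADHD; 200 motion-affected edges
(5 edge-units per mm); eight measures in three construct families (3
working / 2 short-term / 3 long-term instruments, loadings 0.7–0.9,
noise sd 0.5), mirroring the instrument counts of the neuropsychological
battery the design emulates. Passing a previous cohort's `truth` to
`simulate_cohort` reuses the planted structure with fresh subjects — the
setting external validation assumes. `simulate_timeseries` generates node
time series in which planted node pairs share a latent signal whose mixing
weight grows with the trait, so the connectome stage can be exercised end
to end.

What the generator does *not* emulate: autocorrelated BOLD dynamics,
task-evoked structure, spatially structured noise, site or scanner
effects, non-linear brain-behavior relations, missing data, and
image-level motion artifacts (motion enters only as the linear confound
the pipeline claims to remove). Passing tests therefore demonstrate that
the pipeline recovers what its own model class assumes — calibration,
leakage-freedom, confound control, and recovery under linear-Gaussian
conditions — not that real fMRI obeys those conditions.

## Numerical choices and degenerate inputs

- Correlation clipping at `|r| = 1 − 1e-7` before `atanh`.
- Partial correlation computed from sufficient statistics (one pass over
  the edge matrix); identical to residual-correlation to machine
  precision, verified in tests.
- Ridge: intercept unpenalized; primal or dual solve chosen by dimension.
- Inner-CV λ ties break toward the smaller λ (`which.min`).
- Wilks' Λ clamped away from 0 before the Rao transform; singular SSCPs
  flagged at p = 1.
- Motion QC treats equality at a threshold as passing (strict `>`).
- `q² < 0` reported as-is, root flagged `NA`.
- Zero-variance measures error by name (a silent drop would change the
  construct definition); zero-variance edges are silently unselectable.
- Permutation p-values use the add-one rule, so `p ≥ 1/(n_perm + 1)` and
  the test is never anti-conservative by construction.

## Problem sizes used by the test suite

The suite runs the full pipeline at reduced scale, chosen so each property
is decided by its statistics rather than runtime: 12–16 nodes for
orchestration and calibration smoke paths, 60 nodes / 172 subjects / 20–50
divisions for recovery and transdiagnostic checks, 90 nodes for map
similarity, 142 nodes (10 011 edges) for selection-rate calibration, and
100 replicate × 100 permutation null studies for p-value validity. The
268-node default remains the generator's study condition and runs the same
code paths.

## Known limitations

- Selection and ridge assume linear effects; non-monotone brain-behavior
  coupling will be invisible at the screening step.
- Motion control removes only the linear motion component at selection; it
  does not adjust the ridge fit itself.
- The group-permutation classification is conservative by design (FDR gate
  at q = 0.001 over few groups); with 200 permutations the smallest
  attainable two-sided p is about 0.01, so "contributes/detracts" calls
  require many permutations to be reachable at strict FDR levels.
- The MANOVA's F approximation is exact only for special dimension
  combinations; tests pin it to `stats::manova` on random data.
- A single cohort's cross-validated q² can drift slightly above zero under
  the null because spurious sample correlations are shared across folds of
  the same cohort; null calibration statements in the tests are therefore
  made across independent cohorts.
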