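---
title: "Methods: directed resting-state network connectivity with restbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed resting-state network connectivity with restbn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restbn)
```

## The model

`restbn` treats the interaction of K resting-state networks as a
linear-Gaussian Bayesian network: a directed acyclic graph in which each
node's series is a linear function of its parents plus independent Gaussian
noise,

$$x_j = \sum_{i \in \mathrm{pa}(j)} w_{ij}\, x_i + \varepsilon_j,
\qquad \varepsilon_j \sim N(0, \sigma_j^2).$$

The model's assumptions, and hence the package's, are: joint Gaussianity of
the node series, linearity of the dependencies, acyclicity of the directed
structure, and independence of successive time samples. The last assumption
is knowingly false for real fMRI (haemodynamics induce autocorrelation);
the simulator's `ar_coef` option exists precisely to measure how much that
violation perturbs the learned structures.

A fundamental caveat of directed Gaussian models is that the likelihood
only identifies a *Markov equivalence class* (same skeleton and colliders
`i -> k <- j` with non-adjacent `i, j`), not every individual edge
direction. Tests therefore compare learned structures via `cpdag_equal()`,
and single reported directions for edges outside any collider should be
read as the search's choice among equally scoring orientations.

## Learning procedure

1. **Standardization.** Each recording's columns are z-scored with the
   population (denominator N) standard deviation. This removes intercepts,
   makes weights comparable across subjects, and makes the empirical Gram
   matrix a correlation matrix. The price is that equal-error-variance
   identifiability arguments no longer apply — another reason all recovery
   claims are stated at the equivalence-class level.
2. **Candidate-parent screening.** For each target node the lasso path of
   the target on all other nodes is computed on a 50-point log-spaced grid
   from the critical penalty (smallest that zeroes all coefficients) down to
   1% of it; each distinct support on the path is refit by least squares and
   scored with the per-family Gaussian BIC; the support at the optimum
   becomes the candidate set. This prunes the move space of the structure
   search without deciding directions.
3. **Structure search.** Greedy hill-climbing over DAGs with add, delete
   and reverse moves, restricted to node pairs allowed by the (symmetrized)
   candidate sets, each move checked for acyclicity, accepting the single
   best strictly improving move. The first climb starts from the empty graph
   and breaks ties deterministically (add < delete < reverse, then
   lexicographic source/target order). Each of the 20 seeded restarts climbs
   from a random acyclic subgraph of the candidate set (edge inclusion 0.3)
   and breaks exact score ties *at random*. The random tie-breaking is
   essential, not cosmetic: for score-equivalent orientations the
   deterministic rule always picks the same direction, and every restart
   then slides into the same moralized local optimum. On the packaged
   9-node networks, 10 deterministic-tie restarts reproducibly stalled a few
   BIC units short of the optimum, while 20 random-tie restarts attain the
   exhaustive-search score on all 4-node benchmark datasets and recover the
   generating equivalence class at N = 4600; that is why 20 is the default.
4. **Weights.** Given the structure, each family is fit by least squares
   without intercept; residual variances use the maximum-likelihood
   denominator N. Score bookkeeping runs on the Gram matrix, so family
   evaluations cost a |parents|-sized solve independent of N, memoised per
   parent set.

The BIC counts `|pa(j)| + 1` parameters per family (coefficients plus the
variance); with standardized data there are no intercepts to count. This
convention changes model selection and is therefore stated explicitly and
frozen in the tests' closed-form expectations.

## Group models, features, significance

The group network of a condition concatenates the individually standardized
recordings of all its subjects and learns one BN, giving a single weight
per edge — chosen over averaging per-subject networks because the
downstream report needs one coherent group graph. Per-recording features
are a full BN learned from that recording alone, flattened source-major
into K² = 81 directed-edge weights with zeros for absent edges; this is the
one construction that naturally yields a fixed-length directed feature
vector per sample. Cross-subject edge significance is a two-sided
one-sample t-test of each edge's weights against zero at α = 0.05,
uncorrected; an identically-zero column (edge never selected) is reported
with p = 1, a nonzero constant column with p = 0.

## Classification protocol

A linear soft-margin SVC (cost C = 1; the cost is deliberately not tuned)
is used throughout. RFE eliminates one feature per iteration — the one with
the smallest absolute hyperplane coefficient, ties removing the higher
column index first — on features z-scored over the full sample; columns
with zero variance get zero weight and leave first. The default protocol
then evaluates each nested top-k subset by leave-one-out accuracy, with
two choices the user controls:

* **LOO unit** — `by_subject` (default) holds out both recordings of a
  subject together, respecting within-subject dependence; `by_sample` is
  classic per-recording LOO.
* **Ranking scope** — the default ranks once on all samples and only
  cross-validates the subset evaluation, which mirrors the common published
  protocol but carries selection bias; `nested_rfe_accuracy()` recomputes
  the ranking inside every training fold for an unbiased estimate.

Fold standardization statistics are computed on the training fold only;
a test asserts agreement with an independently coded fold loop.

## The synthetic cohort

The generator emulates the study conditions the pipeline is designed for:
20 subjects, two conditions per subject, 230 timepoints per recording
(240 acquired volumes minus 10 discarded) at TR = 2 s, 9 nodes. Ground
truth is the packaged pair of condition-specific networks; subject
variability is Gaussian jitter (sd 0.1) on the nonzero weights only, so
every subject shares the group structure — there is no published
subject-level generative description to copy, and structure-preserving
jitter is the simplest choice consistent with a common group graph. Noise
is unit variance for every node. Per-recording seeds are drawn once from
the master seed, making cohorts bit-reproducible.

What the generator does *not* emulate: haemodynamic convolution,
physiological noise, head motion, scanner drift, or spatial structure
beyond idealized sphere ROIs (the volume renderer places the node signal
uniformly inside each sphere on a 3 mm grid plus white background noise).
Passing tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to everything real data does.

## Numerical choices

* **Band-pass filter** (0.01–0.08 Hz default): linear detrend followed by an
  ideal rectangular frequency mask with inclusive band edges, then
  orthogonalization against the band-limited image of the linear ramp. The
  last step makes the composite an orthogonal projection, so filtering is
  exactly idempotent; without it a second application's detrend would shift
  the result by the small trend of the band-limited signal.
* **Sphere masks**: a voxel belongs to a node if its centre lies within the
  radius (ties at the boundary included via a 1e-9 slack); masks may be
  clipped by the grid but must be non-empty.
* **Nuisance regression** runs at node level after extraction; because both
  averaging and regression are linear, this equals voxel-level regression
  followed by averaging (asserted to 1e-8). Confounds are band-pass
  filtered with the data so regression cannot reintroduce stop-band energy.
  Collinear confound columns are dropped with a warning.
* **Degenerate inputs**: zero-variance node columns abort standardization
  with the node named; near-singular family solves raise rather than
  silently regularize; residual variances are floored at 1e-300 inside the
  log only.
* **Head-motion thresholds** (1 mm, 1°) are reported as a flag per
  recording, never auto-excluding.

## Problem sizes in the tests

The suite exercises: implied-covariance agreement at T = 50 000 (2% of the
covariance scale), equivalence-class recovery at N = 4600, weight recovery
at N = 50 000 (oracle = population standardized coefficients from the
implied covariance), exhaustive-search agreement on 50 four-node datasets
(543 labelled DAGs each), five 20-subject cohorts for the discrimination
claim, and a 10-subject condition-identical cohort with 50 label
permutations for null calibration. These sizes were chosen so each claim is
sharp at conventional simulation scales.

## Known limitations

* Single-direction reporting for non-collider edges reflects search
  tie-breaking, not evidence (see above).
* The per-recording BN features are sparse and slightly unstable at
  T = 230; edges near the detection threshold appear for some subjects
  only, which the cross-subject t-test then adjudicates.
* The default protocol's accuracy curve inherits RFE selection bias by
  construction; use the nested variant when an unbiased number matters.
* No time-lagged (dynamic/causal) modelling: the BN captures
  contemporaneous conditional dependence only.
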