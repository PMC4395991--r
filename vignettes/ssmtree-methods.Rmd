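---
title: "Covariance-pattern features and decision trees for FDG-PET classification"
author: "ssmtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-pattern features and decision trees for FDG-PET classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmtree)
```

## The problem

Parkinsonian syndromes — Parkinson's disease (PD), multiple system atrophy
(MSA), progressive supranuclear palsy (PSP) — are hard to tell apart early,
yet each is associated with a characteristic spatial pattern of cerebral
glucose metabolism visible in FDG-PET. `ssmtree` implements a complete
pipeline for this setting: extract metabolic covariance patterns and
per-subject expression scores from a cohort of brain volumes (the scaled
subprofile model, SSM/PCA), classify subjects from those scores with a
decision tree whose structure a clinician can read, and validate the result
with leave-one-out cross validation and a permutation test.

## The SSM/PCA model

Let $P_{sv}$ be the masked subject-by-voxel intensity matrix ($s = 1..M$
subjects, $v = 1..V$ voxels). The model assumes tracer uptake is
multiplicative — a per-scan global factor times regional modulation — so all
structure is extracted in log space:

1. **Mask.** Each subject's voxels below 35% of that subject's whole-brain
   maximum are removed; voxels exactly at the threshold are kept (only
   intensities *less than* the threshold are discarded). Subjects must share
   one voxel space for PCA, so the per-subject masks are intersected.
2. **Log transform.** $L_{sv} = \ln P_{sv}$.
3. **Double centering.** Subtract each subject's row mean (the global
   scaling factor), then subtract the column mean of the row-centered
   matrix — the *group mean profile* (GMP). The residual is the *subject
   residual profile* matrix $\mathrm{SRP}_{sv}$, with all row and column
   means zero.
4. **PCA.** Eigendecomposition of $\mathrm{SRP}\,\mathrm{SRP}^\top$ (an
   $M \times M$ problem) yields, for each retained component $k$, a
   unit-norm voxel pattern — the *Group-Invariant Subprofile*
   $\mathrm{GIS}_k$ — and a subject score
   $z_{sk} = \mathrm{SRP}_{s\cdot} \cdot \mathrm{GIS}_k$ measuring how
   strongly subject $s$ expresses pattern $k$.

An unseen subject is projected onto a trained model by reusing the training
mask and GMP: extract the masked voxels, log, remove the subject's own mean,
subtract the training GMP, and take dot products with the stored patterns.
This is what makes honest cross validation possible — nothing about a test
subject enters the training-side quantities.

Because scores are defined through the whole dataset's PCA, removing or
adding one subject changes everybody's scores. Validation therefore refits
the entire extraction per fold (`extract_folds()`, `loocv()`), rather than
computing scores once.

### Numerical choices

* Components with eigenvalue below $10^{-10}$ of the largest are dropped;
  double centering removes at least one rank, so $K \le M-1$.
* The sign of an eigenvector is arbitrary. Each pattern is flipped so its
  largest-magnitude voxel loading is positive, making stored models and
  tree thresholds reproducible.
* Scores are raw projections — never z-scored — so tree thresholds are on
  the natural score scale.
* Voxels are flattened in fixed grid order (first coordinate fastest).
* Natural logarithms throughout.

## The C4.5 tree

The classifier is a from-scratch C4.5 on continuous features. At each node,
every threshold between consecutive distinct values of every feature is a
candidate; a candidate must leave at least `min_cases` (default 2) cases in
both branches and have information gain at least the mean gain of the
admissible candidates (C4.5's guard against spuriously high ratios); among
those, the split with the highest gain ratio (gain divided by the split's
own entropy) wins, with ties resolved to the smallest threshold. The
reported threshold is the largest observed value not above the bracketing
midpoint, so every printed threshold is a value occurring in the data.
Recursion stops at pure nodes, when fewer than `2 * min_cases` cases remain,
or when no admissible split exists; leaves take the majority class, ties
going to the lexicographically first label.

Pruning is pessimistic and bottom-up: a subtree collapses to a leaf when the
leaf's pessimistic error — case count times the upper confidence bound of
its error rate — does not exceed the summed pessimistic errors of the
subtree's leaves. The bound for $E$ errors in $N$ cases is the exact
inversion of the binomial tail, $U$ such that $P(X \le E \mid N, U) = cf$,
i.e. `qbeta(1 - cf, E + 1, N - E)`; for $E = 0$ this reduces to the classic
$1 - cf^{1/N}$. The bound is clamped at the observed rate $E/N$, so at
$cf = 1$ it equals the observed error and nothing that helps on the training
data is pruned; the default $cf = 0.25$ prunes at conventional strength.
Subtree-raising (grafting the most populous branch) is not implemented:
leaf replacement alone keeps pruning monotone and idempotent, which we
verify by property test. Later C4.5 releases also penalize continuous
attributes by $\log_2(N-1)/N$; that correction is deliberately omitted and
documented here. Missing-value fractionalization is unnecessary because
subject scores are always complete.

## Component preselection

Two preselection rules mirror common practice:

* **Variance order** — keep the first $\lceil f K \rceil$ components by
  eigenvalue (ceiling, so a tiny fraction still keeps one component).
* **AIC** — rank components by the AIC of a single-feature two-class
  Gaussian classifier (class-conditional means, pooled variance, $k = 3$
  parameters). The likelihood entering the AIC is the classifier's
  likelihood of the observed *labels* — the product of posterior
  probabilities assigned to each subject's true class. An AIC on the
  feature's own class-conditional density would be scale-dependent and
  essentially blind to discrimination (the within-class residual variance
  of an informative component and of a noise component are the same);
  the label likelihood is scale-invariant and measures exactly what
  preselection needs. This interpretation is a design choice: the
  criterion's name fixes the penalty form, not the model.

Selection always happens inside the training fold, on training scores only.

## Validation

**LOOCV.** Each fold removes one subject, rebuilds the mask, refits the
SSM/PCA model, reselects components, refits the classifier, projects the
held-out subject, and predicts. Performance is the percentage of correct
predictions over the $M$ repetitions. Sensitivity and specificity follow
the conventions of the clinical tables this pipeline produces: sensitivity
is the fraction of the *reference* group (healthy controls, or the first
disease group in disease-vs-disease comparisons) correctly classified,
specificity the fraction of the remaining (patient) rows correct. With more
than two classes only per-class accuracies are reported.

**Permutation test.** The observed performance $P_O$ is compared with
$P_1..P_{N_\mathrm{perm}}$ obtained by shuffling labels uniformly (no
stratification — class sizes are preserved by the shuffle itself) and
re-running the full cross validation; $p = \#\{P_i \ge P_O\}/N_\mathrm{perm}$,
significant below 0.05. Feature extraction is unsupervised, so the per-fold
models are computed once and reused across permutations; the predictions
are bit-identical to re-running the refits per permutation, only cheaper.

A behaviour worth knowing: under the null, LOOCV performance of adaptive
classifiers is *pessimistically biased below* the nominal chance level.
Removing one subject leaves its class in the minority of the training fold,
so a tree that collapses toward the majority systematically votes against
the held-out case (the extreme case is a majority-only classifier on a
balanced two-class cohort, which scores 0% under leave-one-out). On our
null cohorts the observed performances centre in the mid-30s rather than at
50%. The permutation test is unaffected — its null distribution carries the
same bias — which is precisely why significance is judged by permutation
rather than against 50%.

## The synthetic cohort generator

No clinical scans ship with the package; every claim is exercised on
synthetic cohorts with known ground truth. For subject $s$ in group $g$,
log-intensity over the foreground ("brain") voxels is

$$\ell_s = \mathrm{gmp} + o_s \mathbf{1} + \textstyle\sum_k z_{sk}\,q_k + \varepsilon_s,$$

with a smooth random GMP field (mean log intensity `log(100)`, spatial SD
0.1 log units), a per-subject global offset $o_s \sim N(0, 0.1^2)$,
mean-removed orthonormal patterns $q_k$, group-dependent scores
$z_{sk} \sim N(\mu_{gk}, \sigma_{gk}^2)$, and i.i.d. voxel noise
$\varepsilon \sim N(0, 0.05^2)$ by default. Intensities are
$\exp(\ell_s)$, so the pipeline's log transform inverts the generative
model exactly and recovery is analytically clean. Background voxels (40% of
the default $16^3$ grid) are set to 1% of the subject's mean foreground
intensity, far below the 35% mask. The default cohort emulates the study
design the pipeline targets: 18 HC, 20 PD, 21 MSA, 17 PSP, one
disease-specific pattern per patient group with expression mean 2.5
(score SD 1).

What the generator does *not* emulate: anatomy, spatially correlated
scanner noise, partial-volume effects, registration error. Passing tests
therefore demonstrate correctness of the algorithms and calibration of the
statistics on data satisfying the model's own assumptions — not clinical
performance.

### Problem sizes used by the test suite

These are the package's reference experiment scales, chosen to be
informative at desk scale:

* Pattern recovery / full-pipeline accuracy: $16^3$ grids, 20 + 20
  subjects, one pattern with group score means $\mp 2$ and score SD 0.5
  (a cleanly separable "strong pattern" cohort: about 8 pooled SDs between
  the groups, matching the construction's premise that the embedded effect
  itself leaves no class overlap), voxel noise SD 0.05, five seeds.
* Null calibration: twenty $8^3$ cohorts of 10 + 10 subjects with no
  embedded pattern, 50 permutations each.
* Classifier comparisons and unit tests run on directly drawn score tables
  (`make_score_table()`), which share the score layer of the volume
  generator but skip image synthesis.

## Open design points, resolved

* **Per-subject vs group mask:** per-subject 35% masks intersected into a
  common space (PCA needs one column space).
* **Centering order:** subject mean first, then GMP — training must match
  the projection pipeline used for unseen cases.
* **C4.5 "default values":** `min_cases = 2`, `cf = 0.25`.
* **Permutation scheme:** label shuffle (class sizes preserved), seeded;
  the seed is recorded in the result object.
* **AIC variant:** plain AIC (no small-sample correction), with the
  label-likelihood reading argued above.
* **No global intensity pre-normalization** beyond the documented steps;
  the subject-mean removal in log space already absorbs global scaling.
* **Comparison harness:** CART, random forest, naive Bayes and the linear
  maximum-margin classifier are backed by `rpart`, `randomForest` and
  `e1071`; k-NN and LDA are implemented in-package to guarantee
  deterministic lexicographic tie-breaking and a ridge-regularized pooled
  covariance ($\lambda = 10^{-6} \times$ mean diagonal; score matrices can
  have nearly as many columns as rows). LDA also supports dropping a
  trailing fraction of features, the workaround used when the covariance
  would otherwise be singular. CART's split thresholds are relaxed to
  `minsplit = 4` because cohorts here are tens of subjects, where rpart's
  default of 20 would refuse to split at all.

## Known limitations

* Performance on real FDG-PET depends on preprocessing (spatial
  normalization, smoothing) that is out of scope here; the package assumes
  registered, positive-valued volumes on a common grid.
* C4.5 with all components and few subjects overfits — the motivation for
  preselection and pruning; expect unstable root features on weakly
  separated groups.
* The LOOCV null bias discussed above means raw performance numbers on
  small cohorts should always be read next to their permutation p-value.
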