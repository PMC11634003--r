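---
title: "Texture-based coral species discrimination: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based coral species discrimination: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coraltex)
```

## The problem

Congeneric scleractinian corals such as the Atlantic *Siderastrea* complex
are notoriously hard to identify: the classical quantitative characters
(corallite and columella diameters, septa counts, inter-columella
distances, septal-cycle completeness) overlap heavily across species and
vary with geography. Experienced taxonomists nevertheless discriminate the
species visually from skeletal micro-texture. `coraltex` implements a
pipeline that emulates that ability: it quantifies skeletal texture from
grayscale micrographs with Completed Local Binary Patterns (CLBP),
classifies samples with a fuzzy associative memory whose output is a
per-species *pertinence* in $[0,1]$, and evaluates classifiers with
replicated cross-validation, one-vs-rest True Skill Statistic (TSS)
sweeps, and a meta-learning assessment based on precision–recall curves.
Because no public micrograph corpus accompanies the problem, the package
ships a synthetic generator of pseudo-corallite textures and morphometric
tables with the statistical structure the analysis assumes, so every stage
is testable offline.

## Texture descriptors

For each pixel $c$ at least $\lceil R\rceil$ pixels from the border, $P$
neighbours are sampled on a circle of radius $R$ (bilinear interpolation by
default), and the local differences $d_p = g_p - g_c$ are decomposed into

* a **sign** bit $s_p = [d_p \ge 0]$,
* a **magnitude** bit $t_p = [|d_p| \ge c]$, where $c$ is the mean of
  $|d_p|$ over all valid pixels and neighbours of the image, and
* a **centre** bit $[g_c \ge c_I]$, with $c_I$ the mean intensity over the
  valid region.

Ties use the $\ge$ convention throughout. Sign and magnitude patterns are
reduced by the rotation-invariant uniform (riu2) map — patterns with at most
two circular 0/1 transitions map to their bit sum, all others to one
non-uniform bin — and the three components are combined in a joint
histogram of dimension $(P+2)\times(P+2)\times 2$, flattened with the
centre bit fastest and L1-normalised. With the default $P=24$, $R=3$ this
yields $26^2\cdot 2 = 1352$ descriptors per image.

Key properties, exercised by the test suite:

* **Illumination invariance.** Every comparison is relative (signs of
  differences, magnitudes against an image-wide mean, centre against the
  image mean), so any affine intensity change $aI+b$, $a>0$, leaves the
  descriptor untouched to machine precision.
* **Rotation invariance.** riu2 bins are invariant to rotations of the
  neighbour ring; under exact 90° image rotations with nearest-neighbour
  sampling the bin multisets are identical.
* **Border policy.** Pixels within $\lceil R\rceil$ of an edge are
  excluded rather than padded, avoiding synthetic edge patterns.

The defaults $(P, R) = (24, 3)$ were chosen because they are the unique
standard configuration whose joint sign/magnitude/centre histogram has
exactly 1,352 cells, the descriptor count the pipeline is designed around;
both are exposed in `clbp_config()`. The two magnification scales of a
survey are pooled as independent images, with the scale kept as metadata.

## The fuzzy associative memory classifier

`theta_fam()` stores every training exemplar as a *fundamental memory*
$a_i$ with weight $v_i \in [0,1]$ and scores a sample $x$ per class $c$
with a competitive layer over an equivalence measure $\theta$:

$$y_c(x) = \max_{i:\ \mathrm{label}_i = c} v_i\, \theta(x, a_i).$$

Two equivalence measures are provided:

* `l1_complement`: $\theta(x,a) = 1 - \tfrac1n \sum_j |x_j - a_j|$, suited
  to min-max scaled measurement vectors (the morphometric characters);
* `fuzzy_jaccard`: $\theta(x,a) = \sum_j \min(x_j,a_j) \big/ \sum_j
  \max(x_j,a_j)$, which preserves the mass-weighting of histogram inputs.

Both are 1 exactly at $x = a$ and bounded in $[0,1]$, so pertinences are
fuzzy memberships: they need not sum to one across classes, and a sample
may be equally pertinent to two species — exactly the behaviour wanted when
the labels themselves are tentative.

Weights are trained by stochastic subgradient descent on the multiclass
hinge loss $\max(0,\ m - (y_{\mathrm{true}} - \max_{c\neq\mathrm{true}}
y_c))$ with margin $m = 0.1$, learning rate $0.05$ and 200 epochs
(deterministic given a seed). When the margin is violated the true class's
best memory is reinforced and the best rival memory suppressed. Weights are
kept inside $[0,1]$: the lower clip keeps scores interpretable as
equivalences, and the upper cap means the final pertinence clip never
activates, so learning acts by *suppressing* memories that confuse rival
classes rather than inflating scores until every class saturates at 1 —
without the cap, weight growth saturates all clipped pertinences at 1 and
the threshold sweep degenerates.

Feature scaling is part of the model: min-max ranges are fitted on the
training set and validation vectors are clipped into $[0,1]$ (they must be
scorable even when outside the training range). For inputs that are already
probability vectors the scaler can be disabled (`scale = FALSE`). In the
pipeline, CLBP histograms additionally pass through the Hellinger map
(element-wise square root) before the fuzzy-Jaccard comparison; this
stabilises the variance of low-mass bins and markedly improves the
separation of the equivalence scores, while keeping inputs in $[0,1]$.

## Baseline classifiers

**DAPC** (discriminant analysis of principal components) handles the
singular, wide CLBP matrix by running LDA with a pooled within-class
covariance on a PCA-reduced space. PCA uses the SVD of the centred
(unscaled) features, since histogram bins share one scale.
`select_components()` picks the number of retained components by k-fold
cross-validation, returning the *smallest* candidate attaining maximal
assignment success; the candidate grid is capped at $\lfloor 2n/3\rfloor$
by default, with a stricter 10%-of-samples cap available
(`cap = "ten_percent"`) since either reading of the conventional rule is
defensible. Posteriors are Gaussian with shared covariance, normalised per
sample; a ridge of $10^{-8}$ is added when the pooled covariance is
singular, with a warning. The deliberate-overfitting regression test (near-
saturated retained space on pure noise) reproduces the instability that
motivates distrusting DAPC's apparent training success.

**χ²-KNN**: majority vote among the $k$ nearest training histograms under
$d(h_1,h_2) = \sum_j (h_{1j}-h_{2j})^2/(h_{1j}+h_{2j})$ (zero-denominator
terms contribute 0), with ties broken by summed inverse distance and then
class order. This is the quick benchmark one runs to check that texture
descriptors carry signal at all.

## Evaluation machinery

One *experiment* is `folds`-fold cross-validation repeated `replicates`
times (`run_cv_experiment()`): per replicate, samples (or whole colonies,
`group_by = "colony"`) are randomly and equitably partitioned within each
class, every sample is scored exactly once by a model trained on the other
folds, and the per-replicate seed is logged for exact replay. The
full-scale design uses 100 replicates; the package default is the
desk-scale 10.

Per replicate the score matrix is **balanced** to the minority-class count
by seeded subsampling, then each class gets a one-vs-rest **TSS sweep**:
response "true label = c", predictor "score for c", predicted-positive at
score $\ge t$, over every distinct observed score plus $\{0,1\}$ (an exact
sweep, not a lattice). TSS = sensitivity + specificity − 1, with the
standard rate definitions; it is prevalence-insensitive, 1 for a perfect
classifier and $\le 0$ at chance. The smallest threshold attaining the
maximal TSS becomes that class's binarization threshold $\tau^*$.
(A published description of this construction swaps the names of the two
rates; since TSS is symmetric in them, nothing changes numerically.)

**Binarization** scores a sample 1 only when the argmax class equals the
true label *and* the winning score reaches that class's $\tau^*$ — so a
correct argmax with an equivocal score does not count, which is the point:
posterior 0.34 vs 0.80 should not be treated alike. Multiclass confusion
bookkeeping assigns each outcome to per-class TP/FN/FP/TN tallies (a wrong
assignment is an FN for the true class, an FP for the predicted one and a
TN for the rest), so performance is always per species, never pooled.

**Meta-learning**: a binary logistic regression of the binarized success on
the winning score, evaluated by one round of stratified 5-fold
cross-validation per replicate and summarised by the area under the
precision–recall curve (step integration $\sum_i (R_i - R_{i-1}) P_i$ with
tie groups handled jointly; success = 1 is the positive class). PRC AUC is
preferred to ROC AUC because it tracks positive predictive ability and is
not inflated by the prevalent negatives. Complete separation (common on
near-perfect replicates) falls back to a ridge-penalised fit (penalty
$10^{-6}$ on the slope); replicates whose outcomes are all 0 or all 1 have
no defined PRC AUC and are reported as `NA`.

Design choices worth making explicit: $\tau^*$ is per-class (a pooled
variant is available through `binarize_outcomes()`); the balanced
subsample is drawn once per replicate; and the meta-classifier uses the
argmax class's score as its single covariate.

## The synthetic generator

`generate_texture_dataset()` renders Voronoi tessellations whose
parameters map onto skeletal anatomy: cell density ↔ corallite density,
radial ridges per cell ↔ septa, darkened boundary walls ↔ theca, a bright
central bump ↔ columella. The **colony is the unit of biological
replication**: each colony draws one multiplicative (log-normal)
perturbation of its class's density and ridge count, and its 6 images
(3 per magnification scale) share it; label noise, when enabled, flips
whole colonies to a designated confusable class with probability ρ. The
corallite scale is rendered as a 3× linear magnification: 1/9 the cell
density with all anatomical lengths 3× larger in pixels, so both scales
carry class signal, as in a real two-magnification survey. Per-image
illumination is a random global gain/offset; a *spatially varying*
illumination field is deliberately not emulated, which keeps the
end-to-end invariance check exact (`gain * I + offset` is affine) — real
SEM vignetting would only be approximately cancelled by CLBP.

The default three classes (20 colonies each, 256² px) differ in corallite
density (16 / 4 / 8.5 cells per 10⁴ px), septa count (24 / 48 / 36) and
wall thickness (3.6 / 1.4 / 2.5 px), with colony-level log-SD 0.02 and
pixel noise SD 0.03 — distinct textures, as the evaluation design assumes.
The default morphometric classes are the opposite regime: class-mean gaps
well under the within-class spread for every continuous character (their
normal-theory intervals overlap pairwise, which the tests assert), with
intratentacular budding moderately diagnostic of one class only. This
contrast is what makes the expected qualitative outcome — texture + fuzzy
classifier clearly ahead of morphometrics + fuzzy classifier — a property
of the *data design*, reproduced by the pipeline rather than assumed.

What passing the synthetic suite does **not** show: robustness to real SEM
artefacts (charging, depth-of-field loss, spatial illumination fields),
to the photographic variability of field-collected skeletons, or to class
structure beyond three species; the generator's textures are far more
homogeneous than real corallites.

## Numerical and degenerate-input policy

* Ties: sign/magnitude/centre bits use $\ge$; argmax ties resolve to the
  first class in the declared order (and are counted); $\tau^*$ ties take
  the smallest threshold.
* Degenerate inputs raise typed errors: images smaller than $2R+1$,
  collinear columella centres, single-class score matrices, outcomes with
  one value (undefined PRC AUC), classes smaller than the fold count.
* Cocircular point sets (e.g. a perfect square) admit two valid
  triangulations; only edge lengths and the min/max distances are
  contracted, not the diagonal's identity.
* Min/max inter-columella distances are read off the Delaunay mesh edges
  (the mesh is computed expressly for that purpose); all-pairs distances
  would give a different, unintended maximum.
* Full determinism: every stochastic stage takes a seed derived from one
  master seed via a fixed integer-hash counter scheme (`seed_stream()`),
  so any single replicate can be replayed in isolation.

## Problem sizes used by the shipped checks

The test suite exercises the full synthetic design at its default size
(3 × 20 colonies × 6 images at 256², 10 replicates of 5-fold CV) once,
memoised across test files; oracle-equivalence checks run on 16×16 images
and ≤ 8-sample score sets, where brute force is exact. The acceptance
script's simulation target uses 1000 replicates of 300 samples. These
sizes are the package's chosen desk-scale design; the full-scale design
(100 replicates) is a single argument away.

## Known limitations

* The fuzzy classifier's training rule is a reconstruction of the
  competitive-hidden-layer architecture from its published description;
  the original equivalence measure and weight objective are not public,
  so agreement is architectural, not numerical.
* Pertinence levels vary between samples (colony effects), so one-vs-rest
  threshold sweeps mix within-sample ranking with between-sample level
  differences; the Hellinger + fuzzy-Jaccard combination mitigates but
  does not remove this.
* DAPC's component selection is the package's own cross-validated
  implementation; it reproduces the method's behaviour, not any specific
  software's output.
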