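---
title: "Keypoint encoding models of pose and viewpoint tuning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keypoint encoding models of pose and viewpoint tuning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseAxes)
```

`poseAxes` fits linear encoding models of single-unit responses to body
stimuli in a keypoint principal-component space, and derives from the fitted
axis everything the downstream analyses need: visualizations, viewpoint
tolerance, variance partitions, clusters and decoders. This vignette
explains the model, the assumptions baked into each stage, the defaults and
why they were chosen, and what the synthetic generator does and does not
emulate.

## The stimulus model

A stimulus is a body pose rendered from a viewpoint. The package represents
it by 22 labeled skeletal keypoints in camera-aligned coordinates: `x`, `y`
in the image plane (origin top-left, `y` downward) and `z` the signed
distance from the frontal plane. The default grid is 45 poses x 8 azimuths
(45-degree steps) x 2 camera elevations (0 and 45 degrees) = 720 stimuli.
One pose class is treated as "hanging": its elevated view is rendered with
the camera displaced downward and looking up by the same tilt, mimicking how
an upside-down body is naturally filmed.

Five design matrices are built from the same coordinates (all divided by the
image size, 350 px by default):

| variant | columns | row manipulation |
|---|---|---|
| `2D` | 44 | none |
| `3D_VD` | 66 | none |
| `2D_VF`, `3D_VF` | 44/66 | views 315/270/225 replaced by 45/90/135 |
| `3D_VI` | 66 | all azimuths replaced by the 0-degree row |

The *view-flipped* construction encodes the hypothesis that a unit responds
identically to mirror-symmetric viewpoints; the *view-invariant* one that it
responds identically to all azimuths of a pose. Because these are pure row
replacements, a model comparison between variants is a comparison between
tuning hypotheses on exactly the same stimuli. The replacement direction for
VF (late azimuths take the early rows) is conventional and a
`direction = "early_from_late"` control is provided; on generic data the two
give rank-equivalent model performances.

Whether the `z` coordinate should share the image-size divisor is a genuine
ambiguity; the package follows the literal reading (every coordinate divided
by 350). Since PCA centers and the regression is scale-equivariant per
column block, this choice only affects the relative weighting of depth
against image-plane variance, and only weakly on our synthetic data.

## Regression, scoring, and the noise ceiling

PCA (column-centering only, never rescaling) is fitted on the **full** data
matrix, as the analysis this package reimplements did, not per
cross-validation fold; the resulting mild train/test sharing affects only
the predictor basis, never the response. A strict per-fold PCA is
deliberately *not* the default because the preferred axis must live in one
fixed basis to be interpretable across folds. Component signs are fixed by
making each component's largest-magnitude loading positive, so inversions
are reproducible across platforms.

Per unit, the stimulus-mean response (200-ms window rates averaged over
trials) is z-scored **globally** across the 720 stimuli and regressed on the
`K = 10` PC scores in 10 seeded, unstratified folds, without an intercept
(the scores are centered and the response has mean zero, so the omitted
intercept is second-order; per-fold z-scoring is available via
`zscore = "per_fold"`). Singular normal equations fall back to an
SVD pseudoinverse at a relative tolerance of `1e-10` instead of failing —
this matters for deliberately redundant predictor banks in the variance
partition. Out-of-fold `R²` uses the held-out mean in the denominator and is
allowed to be negative.

Scores: `R²` (fold mean), `R²_adj = 1 − (1−R²)(N−1)/(N−M−1)` for
inter-model comparison at different `M`, and reliability-normalized versions
obtained by dividing by the Spearman-Brown corrected split-half reliability.
The normalization treats the split-half reliability as the fraction of
response variance that is stimulus-driven; for a unit whose tuning the model
captures perfectly, `R̃²` is ~1 regardless of firing-rate noise. The
package averages 100 seeded random splits (the single-split estimator is
available through `nSplits = 1`); odd trial counts assign the extra trial to
a random half per split.

Three permutation nulls are implemented: label shuffling before the full CV
refit (the primary null), shuffling only held-out labels after fitting, and
permuting the fitted coefficients across components. The first two are
centered below zero — a spurious fit generalizes worse than the held-out
mean — which is why observed scores separate cleanly from them.

## Unit selection

Six screens combined with an AND, all thresholds configurable
(`selectionThresholds()`): split-plot responsivity ANOVA (window as repeated
factor, stimulus as between-presentation factor; pass if main effect *or*
interaction p < 0.05), Fano-factor slope < 4 (OLS of per-stimulus count
variance on mean count), maximal mean net rate > 5 spikes/s, Kruskal-Wallis
selectivity p < 0.05, split-half reliability > 0.5, and — when a
body/face/object category test is present — Body Selectivity Index >= 0.33
with a significant category response. With two window levels the split-plot
ANOVA reduces exactly to an analysis of per-presentation difference scores;
the implementation uses that reduction (verified against `aov`'s
`Error()`-stratum output in the test suite) because the naive dummy-coded
model matrix at 720 stimuli x 6 trials x 2 windows is needlessly large.

## Inversion and the view invariance index

The preferred axis `β̂` maps to keypoint space as `t̂ = Pβ̂`; reshaped to
22 x 2 (or 3), its row norms are the keypoint contribution weights.
Significance of each weight uses label permutations with BH-FDR across the
22 keypoints; following the display convention of the source analysis,
non-significant weights are zeroed *before* max-normalization (the
alternative order changes only the color scale, not which keypoints show).
Null refits use the full CV protocol by default; a single full-data fit per
permutation (`refit = "full"`) is offered because at permutation counts
large enough for BH resolution (>= ~400 for 22 keypoints at FDR 0.05) it is
an order of magnitude cheaper and equally calibrated in our tests. Note a
geometric caveat verified in the tests: an axis planted on two keypoints is
generally *not* representable inside the top-10 PC subspace, so its keypoint
image smears onto kinematically coupled neighbors; recovery claims are
therefore about dominance and significance of the planted keypoints, not
exact support recovery.

The view invariance index of a fitted unit takes the model responses
`ŷ = (X − X̄)Pβ̂`, finds the (pose, elevation) with the maximal response,
and compares the response range over its 8 views (`r_o`) with ranges of
1000 seeded random draws of 7 responses from the 712 stimuli outside that
combination plus the maximum itself: `VII = −(r_o − μ_null)/σ_null`. The
"remaining" pool excludes all 8 best-combination views (that is what makes
it 712 of 720); draws are without replacement; ties in the maximum break to
the lowest stimulus index. VII is invariant to positive affine transforms of
`ŷ`, is reported only for units with unnormalized `R² > 0.25` in population
summaries, and is computed from model responses (a raw-rate variant can be
obtained by passing rates directly to `computeVII`).

## Population analyses

**Variance partitioning.** For two predictor banks fitted separately and
concatenated (identical fold seeds), `unique_A = R²_comb − R²_B`,
`unique_B = R²_comb − R²_A`, `shared = R²_A + R²_B − R²_comb`. Components
can be negative because cross-validated `R²` is not monotone in predictor
count; they are reported as-is.

**Clustering.** Preferred axes of units passing the `R² > 0.25` gate are
clustered with HDBSCAN (`min_cluster_size = 2`, `min_samples = 2`,
Euclidean distance in `β̂` space). No R implementation being available among
the package's allowed dependencies, the algorithm is implemented in-package
(mutual reachability, single-linkage tree, condensation, excess-of-mass
extraction with the root excluded) and is cross-checked against
`sklearn.cluster.HDBSCAN` in the test suite; the one deliberate divergence
is the fully degenerate input of coincident points, which this package
reports as a single cluster rather than all-noise. Each cluster is
summarized by its medoid and the quartiles of `R²` and VII.

**Decoding.** Pose is decoded irrespective of viewpoint: all 16 views of a
pose share its label, pseudo-population trials are built per resample by
independently shuffling each unit's presentations of a pose (so the
concatenated vector mixes views — the construction that makes the task
view-tolerant), and a leave-one-pseudo-trial-out max-correlation classifier
assigns the class whose training-mean template correlates (Pearson) best
with the test vector, ties broken to the lowest class index. Accuracy and
the predicted x true confusion matrix (columns sum to 100%) are averaged
over 50 resamples by default; the permutation test reruns the entire
procedure on label-permuted data and reports the maximum accuracy over
permutations. A linear SVM variant (`e1071`, cost 1, its native multiclass
scheme) is provided for comparison.

## The synthetic generator: what it does and does not emulate

Simulated units are linear-nonlinear-Poisson: mean rate
`max(0, baseline + gain · z_sᵀ β_true)` with `β_true` uniform on the unit
sphere of the chosen variant's PC space, Poisson spike counts over the
200-ms response window (Gaussian and noise-free options exist). The
rectification keeps Poisson rates valid and is negligible when the baseline
(default 10 spikes/s) dominates the drive. `gain` is calibrated by bisection
so the median split-half reliability of the population hits a target
(default study condition 0.7, matching the order of real reliabilities in
the recorded populations this pipeline was designed for); calibration uses a
fixed internal noise seed so it is deterministic, and tolerates ±0.05.

The generator reproduces the *statistical structure the analysis assumes* —
a factorial pose x viewpoint grid, units tuned along fixed axes in keypoint
PC space, trial noise with Poisson mean-variance scaling, a 20/20/20
body/face/object category test. It does **not** emulate photorealistic
bodies (silhouettes are rasterized stick figures), the avatar's actual
poses (classes are synthetic joint-angle distributions, mutually
distinguishable but arbitrary), temporal spike structure, adaptation,
correlated noise across units, or nonlinear mixed selectivity. Passing tests
therefore certify the pipeline's correctness and calibration under the
model's own assumptions, not that cortical units are linear in keypoint PCs.

## Numerical and scale choices

Deterministic seeds flow through every stochastic step (`withr::with_seed`;
derived child seeds stay below 2^31). Degenerate inputs fail loudly with
typed messages (`invalid-argument`, `insufficient-data`,
`undefined-correlation`, `degenerate-null`, `calibration-failure`). The test
suite runs at desk scale: the full 720-stimulus grid wherever structure
matters, an 8-pose (128-stimulus) grid for algebraic properties, 50-unit
populations for recovery and dissociation checks, 100 units for the
two-construction equivalence, and 200-1000 permutations/resamples depending
on the resolution a check needs; the full suite completes in about a minute
on one CPU. `runPipeline(defaultRunConfig(testMode = TRUE))` lowers
permutation and resample counts but never changes a formula.

## Known limitations

* The equivalence of the two view-flipped constructions requires the
  equated PC scores to be re-centered (no intercept in the regression);
  `equateViewScores()` does this by default.
* HDBSCAN with `min_cluster_size = 2` fragments large diffuse groups into
  small clusters when no coarser split survives the excess-of-mass
  criterion — a property of the algorithm (the root cluster is never
  selectable), shared with the reference implementation.
* Variance partitioning against the pixel bank inherits the surrogate
  feature bank's limits: random projections of stick-figure silhouettes are
  a stand-in with the same matrix interface as a CNN activation bank, not a
  model of one.
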