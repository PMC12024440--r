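---
title: "Edge-centric connectivity, community overlap, and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric connectivity, community overlap, and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Conventional functional connectivity summarizes the relation between two
regional signals by one number, their Pearson correlation. The edge-centric
view unrolls that summary in time. Given N component time series, each
z-scored (population convention: divide by T), the **co-fluctuation edge
time series** of the pair (i, j) is the element-wise product

  c_ij(t) = z_i(t) · z_j(t),

positive at frames where the two components deviate from baseline in the
same direction. The time average of c_ij is exactly the Pearson correlation
r_ij — which is why this package insists on the population variance
convention: with the sample (T − 1) convention the identity holds only
approximately, and the identity is used as a test oracle throughout.

For N components there are M = N(N − 1)/2 edges, stored in a fixed
canonical order (row-major over the strict upper triangle, i < j). The
**edge functional connectivity** (eFC) between edges e and f is the
uncentered cosine similarity of their co-fluctuation series,

  eFC(e, f) = Σ_t c_e(t) c_f(t) / sqrt(Σ_t c_e(t)² · Σ_t c_f(t)²),

computed literally as printed — no mean removal is applied to edge rows.
The result is a symmetric M × M matrix with unit diagonal and entries in
[−1, 1].

**Edge communities.** Rows of the eFC matrix (each edge's full
connectivity profile) are clustered with k-means. "Standardized Euclidean
distance" is realized as feature standardization — every eFC column is
centered and scaled to unit sample variance before ordinary Euclidean
k-means — because weighted-distance k-means has no standard centroid
update and rescaling the feature space is the conventional equivalent.
Lloyd's algorithm with k-means++ initialization runs `n_restarts` times
(study-scale default 250) per k over a sweep (default k = 2…10), and the
restart with minimum within-cluster sum of squares (inertia) wins; ties go
to the first restart. A restart producing an empty cluster re-seeds the
offending centroid at the point farthest from its centroid, at most 10
times, then errors. Every partition records the seed of its winning
restart; re-running `cluster_edges()` with `n_restarts = 1` and that seed
reproduces the labels bit-for-bit.

No single k is privileged a priori: entropy is computed for **every** k in
the sweep, and the pipeline's default "selected k" is the elbow (largest
relative drop) of the cohort-mean normalized inertia curve, recorded
prominently in the manifest.

**Community overlap.** From a partition g of the edges, the participation
of node i in community c is p_ic = (1/(N−1)) Σ_{j≠i} δ(g_ij, c), a
probability vector over communities. Its Shannon entropy
h_i = −Σ_c p_ic log₂ p_ic, normalized by log₂(k), measures how evenly
node i's edges spread over communities: 0 when they share one community,
1 when they are spread uniformly. The normalization denominator uses the
*requested* k, not the number of non-empty communities, so values remain
comparable across subjects sharing a sweep; 0·log 0 := 0. Network-level
entropy is the unweighted mean over member components (a weighted mean is
available via `weights`), and the long-format entropy table
(subject × level × unit × k) is the unit of all group statistics.

Community similarity between nodes i and j is the fraction of the N − 2
third-party nodes u whose edges to i and to j carry the same label,
s_ij = (1/(N−2)) Σ_{u≠i,j} δ(g_iu, g_ju); the diagonal is stored as 1 by
convention and excluded from statistics.

**Group statistics.** Confounders are handled by pooled OLS
residualization: each unit's entropy is regressed on an intercept plus the
named covariates over all subjects (the group label is never in the
design), and the residuals enter a classical pooled-variance two-sample t
test (Welch available by flag). Bonferroni control uses α/n with n equal
to the number of units in the family — 16 networks at one k by default;
testing several k multiplies the family, and the family size is always
recorded in the output. Demographic count tables use Pearson's χ² without
continuity correction (Yates by flag); on the emulated study's sex table
(24M/9F vs 24M/20F) the uncorrected form reproduces the published
p = 0.103 to three decimals. Effects are signed group2 − group1 with group
labels in alphabetical order.

Because no single k is privileged, `compare_groups(..., k = "mean")` tests
each subject's entropy averaged over every k in the sweep. This sweep-mean
is the package's preferred overlap summary for simulation benchmarks (see
below) and is recorded with the sentinel k = 0 in output tables.

## The synthetic cohort generator

The study this package emulates did not deposit its fMRI data, so every
claim about recovery is made against a latent-factor generator with
analytically known ground truth — a *stand-in for the statistical
structure the entropy analysis assumes, not a model of BOLD physiology*.

k\* independent standard-normal latent community signals s_c(t) drive node
i as x_i(t) = Σ_c w_ic s_c(t) + noise_sd · ε_i(t), with nonnegative
loadings summing to 1 per node. Defaults mirror the emulated study where
desk-feasible: 32 components over the 16 canonical intrinsic connectivity
networks (2 each), T = 230 usable frames (240 acquired minus 10
discarded), cohorts of 33 ("patient") and 44 ("control"; the source
study's abstract and its participant table disagree about which cohort is
which — we follow the participant table), k\* = 4, primary loading 0.85
with geometrically decaying cyclic secondaries (decay 0.4), noise_sd 0.5.
Covariates emulate the study's demographic profile: group-matched age, a
mild sex-proportion difference, and genuine group shifts in education and
a symptom score, so residualization has real confounding to remove.

Two planted edge labelings are reported:

* `edge_labels` — argmax_c w_ic·w_jc with ties to the lowest index. This
  scores only the *shared single-community* content of an edge.
* `edge_pair_labels` — argmax over the symmetrized latent-pair
  coefficients A_(c,d) = w_ic w_jd + w_id w_jc (and A_(c,c) = w_ic w_jc).

The distinction matters. The co-fluctuation of an edge between two
different communities a and b is dominated by the interaction term
s_a·s_b — with primary loadings 0.9 its coefficient is 0.81, an order of
magnitude above any shared single-community term — so cross-community
edges form their *own* eFC blocks. A k-means on eFC therefore recovers the
latent-pair partition, not the single-community argmax; with k\* = 2 the
pair partition has exactly three communities (within-1, within-2, cross),
which is the package's planted "three-community eFC" benchmark, recovered
with ARI = 1 at zero noise and ARI ≥ 0.9 at noise_sd = 0.5, T = 400.
Recovery benchmarks are evaluated against `edge_pair_labels`; the
single-community labeling is retained because it is the natural reading of
"the community of an edge" at the node level.

**Why overlap needs a heterogeneous population.** A node's incident edge
rows all share the node's own realized signal, so near-ties in their
community content break *coherently*, not independently: in a homogeneous
cohort a single strongly-mixed node's edges tend to move together and its
measured entropy barely responds to its planted overlap. Recovered
entropy tracks planted overlap only when the population itself spans a
range of mixing — which the `mixing` argument provides, pulling each
network's loadings toward the uniform mixture by a per-network amount.
The benchmark world uses `mixing = seq(0, 0.75, length.out = 16)` (one
component per network at desk scale) and measures overlap with the
sweep-mean entropy; the planted group effect sets the target network's
loadings fully uniform in group 2. Under that stated world the pooled
Spearman correlation between recovered and planted node overlap is ≈ 0.75
(threshold 0.7), the planted network is detected as the unique Bonferroni
hit with high power, and 50 null cohorts keep the family-wise error
within its binomial margin of 0.05.

What a green test does **not** establish: the generator has no
autocorrelation, no hemodynamics, no motion artifacts, and independent
Gaussian noise, so recovery rates here are upper bounds on what real BOLD
data would allow; conversely the entropy's insensitivity to overlap in
*homogeneous* populations is a genuine property of product-based edge
construction, worth keeping in mind when interpreting empirical entropy
differences.

## Numerical and design choices

* **Variance convention**: population (÷T) everywhere a z-score is taken;
  makes mean(c_ij) = r_ij exact (tested at 1e−10).
* **Canonical edge order**: row-major upper triangle, 1-based; closed-form
  bijection both ways, tested exhaustively to N = 50.
* **eFC memory**: the dense double M × M matrix for N = 200 is ≈ 3 GB;
  `compute_efc(block_size=)` evaluates the Gram product in row blocks, and
  desk-scale tests use N ≤ 40.
* **k-means determinism**: per-restart seeds derived from the master seed
  by a fixed rule; identical input + seed gives identical labels; with a
  single restart the master seed is used directly so ledgered partitions
  replay exactly.
* **Degenerate inputs**: constant component rows are rejected by name
  (z-score undefined); zero-norm edge rows are rejected with their node
  pair (eFC denominator); k = 1 with normalized entropy is rejected
  (log₂ 1 = 0); χ² with a zero marginal is rejected.
* **Elbow rule**: largest relative inertia drop (I(k−1) − I(k))/I(k−1) on
  the cohort-mean normalized curve — a reportable default, not a claim
  that the elbow k is "true".
* **Residualization without the group term** deliberately follows the
  conservative reading of "confounders were controlled for": a covariate
  that is itself group-shifted absorbs part of the group effect
  (attenuation, not inflation). The alternative — covariates plus a group
  dummy in one linear model — can be assembled from `two_sample_t()` on
  `lm` residuals by the user; the default is the documented one.
* **Config format**: JSON (the R YAML parser is not a dependency of this
  package); unknown keys are rejected to catch typos.
* Matrices persist as delimited text with JSON sidecars rather than binary
  blobs: byte-stable, diffable, and sufficient at desk scale.

## Known limitations

* Per-subject k-means at study scale (M = 19 900, 250 restarts × 9 k) is
  compute-heavy; the implementation is honest Lloyd's in R and will want
  hours, not minutes, at that scale.
* The pooled ("group-mean eFC") clustering mode shares one partition
  across subjects, so between-subject entropy variance is zero by
  construction and group statistics are skipped in that mode.
* No consensus clustering, no modularity-based edge communities, no
  time-resolved event analysis, no FDR alternatives to Bonferroni — out of
  scope by design.
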