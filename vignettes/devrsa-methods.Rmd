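---
title: "Models and methods behind devrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devrsa)
```

devrsa studies how category-selective cortical representations reorganize
between childhood and adulthood. Its inputs are per-subject, per-run
response-pattern matrices — t-values over the vertices of a region of
interest, one column per run x condition — together with subject metadata
(age group, hemisphere, region). Because such pattern archives come from a
long acquisition and preprocessing chain that is out of scope here, the
package ships a synthetic-cohort generator whose statistical structure
matches what the analyses assume; every pipeline stage is exercised against
it in the test suite.

## The synthetic cohort generator

`generate_cohort()` simulates two groups (children and adults, 30 each by
default), three localizer runs, five categories (faces, bodies,
pseudowords, places, objects; two subcategories each, e.g. child and adult
faces), two hemispheres and two regions (VLPFC and VTC), 500 vertices per
region by default. The signal model for a condition's pattern is

* a region-level **category template**: a shared *animate* component added
  to faces and bodies, a shared *inanimate* component added to places and
  objects and, at half weight, to pseudowords, plus a category-private
  component (weight 0.7) for faces, bodies, places and objects, all scaled
  by `animacy_strength`; and a pseudoword-private **word axis** scaled by
  `word_axis_strength`;
* **contrast centering**: the five category templates are mean-centered
  across categories per vertex, because the archives represent
  "preferred > all others" contrasts. This is what makes between-category
  correlations negative on average (as seen in real contrast maps) rather
  than zero;
* a **subject idiosyncrasy** pattern per condition, constant across runs
  (SD `subject_noise_sd`, default 0.5), which creates reliable but
  subject-specific structure — the quantity that geometric dispersion and
  cross-subject decoding are sensitive to;
* independent **run noise** (SD `run_noise_sd`, default 1), the only
  component that differs between runs, hence the quantity that
  leave-one-run-out reliability is sensitive to.

Subcategory templates are the parent template plus a perturbation whose SD
is a fixed fraction (0.25) of the template SD: subcategories are combined
within contrasts but act as distinct "items" in distance analyses.
Synthetic t-values are the pattern values themselves; no GLM is simulated,
since every downstream statistic consumes t-maps as given.

Two design points deserve emphasis. First, giving pseudowords a half-weight
share of the inanimate component makes the animate–inanimate bipartition
({faces, bodies} vs {pseudowords, places, objects}) the *strict* analytic
optimum whenever only `animacy_strength` is positive; had pseudowords
carried no block component they would sit symmetrically between the groups
and the generating partition would only tie for first place. Second, with
all structure strengths and the idiosyncrasy SD at zero the patterns are
exchangeable noise, so within-category minus between-category correlation
is exactly zero in expectation — the property the type-I-error calibration
tests rely on.

Default strengths encode the study conditions the analyses are designed to
detect: strong bilateral animacy structure in VTC at every age, right-VLPFC
animacy present in children (0.5) and stronger in adults (1.0), weaker
left-VLPFC animacy, and a left-lateralized word axis (0.8) already present
in childhood. Strengths are unitless ratios relative to unit run noise.

What the generator does **not** emulate: hemodynamic time series, cortical
geometry and spatial autocorrelation beyond the category-level block
covariance, vertex misalignment across subjects (synthetic cohorts share a
vertex index space; real data would need a common surface space), or
realistic ROI boundaries (ROI labels are contiguous index blocks). Passing
tests therefore demonstrate correctness of the *analyses* under the
assumed generative structure, not robustness to the full messiness of real
imaging data.

## Cross-validated similarity

`loro_similarity()` correlates, for each fold, the held-out run's pattern
for category *i* with the mean over remaining runs of category *j*
(higher SNR on the training side than run-vs-run averaging, which remains
available as `method = "run_vs_run"`). Fold matrices are symmetrized by
`(M + t(M))/2` and then averaged; raw correlations are averaged by default
(`fisher = TRUE` switches to Fisher-averaged). Block statistics exclude the
diagonal, since within-category reliability is reported separately. A
zero-variance pattern is an error naming the run and condition rather than
a silent `NA`.

## Partition models

`enumerate_partitions()` supports three families: the 15 full bipartitions
of five categories, the 90 unordered pairs of disjoint non-empty groups
(partial coverage allowed), and the 75 such pairs that leave at least one
category unassigned — the only natural enumeration of two-group divisions
whose count is 75 ((3^5 − 3·2^5 + 3)/2, assignments surjective onto
{group A, group B, excluded}). Scores are Pearson correlations between the
15 unique cells (5 diagonal + 10 off-diagonal) of the model matrix and the
similarity matrix; the diagonal is included because within-group coherence
includes reliability, and a similarity matrix numerically equal to the
model then scores exactly 1 (`cells = "offdiag"` disables this). Binary
{1, 0} coding is presentation-only: Pearson scores are invariant to affine
recodings. Percentiles are rank/N, the convention consistent with all
three printed (rank, percentile) pairs the ranking reproduces (1/75 =
0.013, 18/75 = 0.240, 11/75 = 0.147). Ties are broken by the canonical
enumeration order (larger first group first, then name).

## Geometry

`embed_patterns()` z-scores each item pattern across vertices, centers the
item x vertex matrix, and takes left singular vectors; component signs are
fixed by making the largest-magnitude vertex loading positive, so runs are
bit-reproducible. PCA is fitted per owner (per subject, or per group-mean
matrix); cross-owner comparisons always go through Procrustes alignment
rather than joint embedding. Items default to the 10 subcategories so that
"distances among faces" is well defined; a 5-category mode exists. The
embedding accepts a single component only for two-item configurations.

`procrustes_align()` implements full Procrustes: translation, uniform
scaling and orthogonal rotation with reflection permitted (the common
default when only distances and similarities are reported; both are
switchable). The Procrustes distance is the residual sum of squares
normalized by the centered target's total sum of squares, which for
optimal scaling equals the symmetric Procrustes statistic
1 − tr²/(‖X‖²‖Y‖²); the test suite verifies exact agreement with an
independent SVD-based implementation. `group_template()` is a
generalized-Procrustes mean: align all configurations to the running mean,
re-average, re-normalize the mean to unit centroid size (guarding against
scale collapse), until movement is below 1e-8 or 100 iterations.
Dispersion is the mean Procrustes distance to the template. Convex-hull
spread is the shoelace area over `chull()` vertices in the first two
components; collinear configurations are an error, not area zero.

## Cross-subject decoding

Observations are per-subject, per-category mean patterns (one row per
subject x category). For each leave-one-subject-out fold a linear
support-vector classifier (hinge loss, cost 1 — fixed, not tuned: a plain
maximum-margin baseline) is trained on the
other subjects with features standardized by training-fold statistics
only. Cluster-level targets (k = 2..5) come from average-linkage
agglomerative clustering on correlation distance of the *training* group's
mean patterns within each fold, so the held-out subject never influences
its own targets.

The permutation null permutes the category-to-label map used for
**training** while evaluating held-out subjects against true labels.
Permuting both sides would merely rename classes and leave accuracy
unchanged; permuting the training side breaks the pattern-label
association, and for 5-way decoding the expected null accuracy is exactly
the expected fixed-point fraction of a random permutation of five labels,
1/5 — matching the chance level the decoding analyses are benchmarked
against. Because the decoder is deterministic in the training map and only
5! distinct maps exist, null accuracies are cached per distinct map; this
is exact, not approximate. P values use the add-one convention
(1 + #{null ≥ true})/(1 + n).

## Stability versus coupling

Per subject and hemisphere, *stability* is the mean correlation between
the vectorized unique cells of each unordered pair of per-fold similarity
matrices from the prefrontal region, and *coupling* is the mean over all
cross-region fold pairs against the posterior region. With three runs,
stability averages 3 pairs and coupling 9 combinations. The signed
identity-line distance is the perpendicular distance
(stability − coupling)/√2, positive when internal coherence dominates.
Category-level coordinates restrict the correlations to one category's row
(its diagonal cell plus four between-category cells). Displacement vectors
are adult minus child category means in this plane; their magnitudes are
tested by permuting group labels across subjects (a design choice — the
original analysis's test is unspecified — labeled as such).

One subtlety, documented in the test suite: leave-one-run-out folds from
the same region share training runs, so their errors are positively
correlated and stability is structurally biased slightly above coupling
even when two regions carry identical structure. The equality of expected
stability and coupling therefore holds for splits with disjoint
measurement noise, and that is the setting in which the package asserts
it.

## Topography

Suprathreshold counts use a strict inequality (t > 2.5 by default,
matching the thresholding convention of selectivity maps). The laterality
index is RH/(RH + LH), so LI(rh, lh) + LI(lh, rh) = 1 exactly. Territory
shares are per-category counts over summed counts — a vertex may be
suprathreshold for several contrasts; winner-take-all assignment is
deliberately not the default since the underlying maps are computed per
contrast. Profile correlations refuse to correlate vectors whose ROI or
category orderings differ rather than silently reordering.

## Tissue trajectories and gene sets

`generate_tissue()` draws per-voxel MTV on the logit scale (guaranteeing
values in (0, 1)) and R1 around an age trajectory: linear
(0.85 + 0.0015·age 1/s, VTC-like steady macromolecular proliferation) or
with a Gaussian adolescent dip (depth 0.08 1/s, centered at 17 years, SD 3
years, right-VLPFC-like). The dip depth was chosen so that the trough
cancels roughly a decade of linear growth — the regime in which child and
young-adult R1 are statistically equivalent, as the developmental
comparison requires — and the slope so that plausible cortical R1 values
(≈0.85–0.95 1/s) span ages 5–54. Inter-voxel R1 SD grows linearly with age
(0.02 + 0.0008·age), and voxelwise R1 follows
α(age) + β(age)·(1/WVF − mean) with β declining from 0.35 at age 5 by
0.004/year, so children show the steeper, more constrained R1–MTV
relation. Age groups bin at 5–10, 11–17, 18–24, 25–54 (inclusive,
exhaustive over [5, 54]; older ages are an error since aging is distinct
from development).

Gene-set curves normalize each gene by its mean over the adolescence
window before averaging within sets. The window is the open interval
11 < age < 20 — the definition used when the normalization was specified —
rather than the wider 11–21 span mentioned elsewhere; it is a configurable
argument. The packaged myelin gene list (PLP1, PLLP, MAG, MBP, CA2, PMP22,
MAL, ERMN, OMG) is deduplicated (MBP appears twice in the source listing).

ANOVAs are balanced two-way factorials with partial
η² = SS_effect/(SS_effect + SS_error); unbalanced designs are rejected
with a clear error because the sums-of-squares partition is then not
unique. Degenerate zero-variance designs report F = 0, p = 1 rather than
NaN. All tests are two-tailed.

## Numerical choices and problem sizes

Tolerances: Procrustes/GPA convergence 1e-8 (movement of the mean shape),
exactness assertions at 1e-9–1e-12, rank detection at 1e-10 of the largest
singular value. Seeds: every stochastic function takes an explicit integer
seed; the pipeline derives per-stage streams from the cohort seed, so a
rerun with the same configuration is bit-identical. The test-suite problem
sizes (typically 30–60 vertices, 5–100 subjects, 100–500 permutations or
replicates) were chosen so the whole suite runs in a few minutes on one
core while keeping Monte-Carlo standard errors small relative to the
margins asserted; the acceptance script uses 200 vertices, 10–20 subjects
and 1000 permutations.

## Known limitations

The generator's vertex correspondence across subjects sidesteps the
surface-registration problem entirely; real use would require a common
space. Only balanced factorial ANOVAs are provided (no mixed or
repeated-measures machinery), no searchlight analyses, no k > 2 partition
families beyond the binary encodings, no nonlinear classifiers, and no
causal coupling estimation. The equivalence of R1/MTV across age groups is
assessed only by non-significant Welch tests, not a formal equivalence
procedure.
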