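---
title: "Group-to-individual similarity of connectivity networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-to-individual similarity of connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgroupsim)
```

## The problem

Resting-state functional connectivity (rsFC) studies overwhelmingly report
group-level statistics: a mean connectivity matrix, a group-level
brain–behavior association. Whether those statistics say anything about a
given individual depends on between-person homogeneity — the ergodicity
requirement. `fcgroupsim` operationalizes that question for connectivity
*strength*: how similar is each individual's Fisher-z connectivity vector to
the group average, and does that similarity moderate how well
connectivity-based models predict the individual's behavioral outcomes?

This vignette documents the models, every tunable parameter that matters,
the synthetic-data generator and its limits, numerical choices, and the
places where the design was genuinely open and a choice had to be made.

## The similarity model: ICC(A,1)

Similarity between the group model g and one individual's vector x over n
connectivity features is the intraclass correlation from a two-way
random-effects model with absolute agreement and single-rater units —
ICC(A,1) in the McGraw–Wong nomenclature. The two raters are {group model,
individual}; the objects are features. This is the only orientation that
yields one ICC per individual. With k = 2:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

where $MS_R$, $MS_C$, $MS_E$ are the object, rater, and residual mean
squares of the crossed layout. Three properties matter in practice:

* **Absolute agreement**: a constant offset between individual and group
  lowers the ICC (`icc_a1(x, x + c) < 1` for c ≠ 0). Rank-order similarity
  alone does not earn a high score.
* **Variance-ratio nature**: the ICC is relative to the between-feature
  variance. Feature sets with little spread (for example, after aggressive
  variance-based selection) yield systematically lower ICCs — a documented
  behavior, not a bug; it motivates the variance-fraction sensitivity
  parameter below.
* **Negative values are legal** and are reported as computed, preserving the
  distributional analyses; there is no truncation at zero.

`icc_a1` is verified against an independent loop-based ANOVA
sums-of-squares oracle to 1e-10 on random instances, and against the
hand-computable case x = (1,2,3,4), y = (2,3,4,5) → 10/13.

Benchmark labels follow the common reliability conventions with closed left
boundaries, an interpretation decision since the published inequalities are
not exhaustive at the cut points: poor < .50 ≤ moderate < .75 ≤ good < .90
≤ excellent.

## Connectivity representations

**ROI level.** Pearson correlations over retained frames for every ROI pair,
Fisher z-transformed (atanh), enumerated row-major over the upper triangle
(i < j in parcellation order). r is clamped to ±(1 − 1e−12) before atanh so
degenerate pairs stay finite — duplicated ROIs in toy data degrade
gracefully rather than producing infinities.

**Network level.** Cell (A,B) is the mean z over all A–B edges (diagonal:
within-network edges). For K networks there are K(K+1)/2 distinct cells.
Cells are means *of z values*, not z of mean r: the z scale is the
analysis scale throughout, group models average z per edge and are never
back-transformed. (Whether the reference analyses averaged r or z at the
network level is not documented; the z-scale reading is consistent with how
the group model is formed and is applied uniformly.)

**Filters, with defaults and units.**

| parameter | default | meaning |
|---|---|---|
| `fd_threshold` | 0.10 mm | censor frames with filtered FD strictly above this; frames exactly at the threshold are retained |
| `min_minutes` | 10 min | inclusion requires retained frames × TR ≥ this (inclusive boundary) |
| `tr` | 0.8 s | seconds per frame |
| `tsnr_sd_k` | 2 (SD) | drop ROIs whose training-mean tSnR falls below grand mean − k·SD; 1 is the stricter sensitivity setting |
| `variance_fraction` | 0.10 | keep the top fraction of edges by between-subject variance, `ceiling(p·E)` edges |
| `n_folds` | 10 | elastic-net CV folds |
| `n_permutations` | 500 | shuffled-network iterations |
| `alpha` | .05 | two-sided level for moderation and JN regions |
| `bonferroni_alpha` | .01 | covariate-screen flag threshold |

The ceiling rule for `variance_fraction` is not arbitrary: it is the unique
rounding rule consistent with all five published sensitivity counts this
package was validated against (173, 861, 1,721, 4,302, 8,603 retained from
a 17,205-edge pool at p = .01, .05, .10, .25, .50). Variance uses the n−1
denominator; ranking is denominator-invariant, so this only matters for
reported values. Ties in the variance ranking break by canonical edge order
(earlier edge wins), making selection fully deterministic.

Both the tSnR ROI set and the variance-selected edge set are computed on
**training subjects only** and reused verbatim for test subjects; test-set
ICCs are always computed against the training-set group model. This
preserves train/test independence, the property that makes test-set
similarity interpretable as population generalizability.

## The permutation null

High network-level ICC could reflect true network structure or could be an
artifact of averaging many edges per cell. The null: per iteration, permute
the ROI→network assignment uniformly at random (network sizes preserved),
recompute every subject's network matrix *and* the training group model
under the same shuffled labels, recompute all ICCs, record the sample mean.
One permutation is shared by the group model and all subjects within an
iteration — the null must break structure while keeping the referent
consistent; resampling labels per subject would additionally break the
comparability of group and individual, which is not the hypothesis being
tested. (Whether the reference implementation shuffled per subject or per
iteration is undocumented; the shared-labels reading follows from the
referent-consistency argument.)

## Prediction and moderation

The elastic net minimizes
$(1/2n)\sum(y - \beta_0 - X\beta)^2 + \lambda[(1-\alpha)\|\beta\|_2^2/2 + \alpha\|\beta\|_1]$
over α ∈ {0.1, …, 1.0} and a data-driven descending λ path, choosing the
(α, λ) with minimum mean CV error ("lambda.min"; the published phrase
"minimum mean standard error" conflates MSE and SE — the lambda.min reading
is the closest literal one and is applied throughout). α = 0 is excluded so
"number of selected features" stays well defined. One random fold partition,
fixed by seed, is shared across the α grid, so the α comparison is paired.
Features are standardized inside the fit on training statistics;
coefficients are reported on the standardized scale; predictions are
invariant to this choice. A model whose selected λ zeroes every coefficient
is flagged *degenerate*: its predictions collapse to the training mean, its
performance r is reported as 0 with the flag attached, and the moderation
stage skips it (mirroring how empty models appear as "–" rows in reports).

Moderation is OLS: `observed ~ predicted + icc + predicted:icc`
(+ covariates as main effects only). Predictors enter **uncentered**: the
`predicted` main effect is then the conditional slope at ICC = 0 and a
coefficient of 1 reflects optimal prediction, and Johnson–Neyman boundaries
live on the raw ICC axis. (The interaction t statistic is invariant to
centering; only main-effect interpretation changes. The uncentered reading
matches how conditional slopes of 1 are interpreted as optimal.) The JN
boundaries solve θ(s)² = t²crit·SE²(s) for the conditional slope
θ(s) = b₁ + b₃s; the quadratic yields 0, 1, or 2 real roots, and
significance labels are only reported inside the observed ICC range.
t_crit uses the fitted model's residual df, two-sided.

Covariate screens regress ICC on each covariate separately (site as
fixed-effect indicators — per-site coefficients from plain linear models,
no multilevel structure), flagged at the stricter α = .01 to limit bias
from partialing.

## The synthetic generator: what it emulates, what it does not

A cohort is a deterministic function of one integer seed:

* **Group structure**: block correlation matrix, default 4 networks × 10
  ROIs, within-network r = 0.35, between-network r = 0.10 — typical
  magnitudes for association-network rsFC after Fisher transform. Repaired
  to the nearest correlation matrix by eigenvalue clipping at 1e−8 and
  diagonal renormalization; if the repair moves any entry by more than
  0.05 the structure is rejected with an error naming the offending blocks.
* **Heterogeneity η ∈ [0,1]**: subject i receives true similarity
  s_i ~ Uniform(1−η, 1) and true matrix s_i·R_group + (1−s_i)·Q_i, with Q_i
  a random correlation matrix from normalized Gaussian factors (full
  support, seedable). η = 0 ⇒ every subject is the group matrix exactly;
  η = 1 ⇒ fully idiosyncratic. The per-subject mixture (rather than one
  fixed mixing weight for all subjects) is what gives the cohort a
  *distribution* of ground-truth similarities for the moderation stage to
  recover; the single-subject operation `sample_subject_matrix` still
  implements the fixed (1−η) mixture for direct use.
* **Time series**: T = 2000 iid multivariate-normal frames (default) plus a
  per-ROI positive mean offset (uniform 80–120, so tSnR is positive,
  finite, and varies across ROIs). Defaults keep edge count (780) ≫
  subjects (120), the p ≫ n regime of real connectome-wide analyses.
* **Motion**: lognormal FD baseline capped below the 0.10 mm threshold with
  spikes injected at `round(censor_fraction·T)` random frames — a heavy
  right tail that exercises the censoring path. The spiked frames' *signal*
  is not corrupted; this is a censoring-logic test bed, not a motion
  simulator.
* **Outcomes**: y_i = β₀ + (c + d·s_i)(w·z_i) + ε_i with defaults β₀ = 2,
  c = 0.5, d = 1, σ = 1 and weight 0.3 planted on 10 random edges of the
  true-matrix Fisher-z features. Multiplicative attenuation (rather than
  similarity-dependent noise) was chosen because it maps exactly onto the
  predicted×ICC interaction the moderation stage tests: under the model,
  the true interaction coefficient *is* d. d = 0 is the null. Outcomes are
  generated from the true subject matrices, so measurement noise enters
  only through the estimated pipeline — ground truth stays ground truth.

**Not emulated**: hemodynamics/BOLD forward models, temporal
autocorrelation, surface geometry, realistic motion artifact, non-Gaussian
signal, site effects on connectivity. Green tests on this generator
establish that the machinery is correct and calibrated (type-I error of the
interaction test inside the 95% binomial band around .05 across 500 null
cohorts; ≥ 90% power at the default SNR; planted-support recovery), not
that any empirical claim holds in real populations — the generator's
homogeneity structure is exactly what real studies must estimate.

## Numerical choices and degenerate inputs

* Fisher clamp at |r| = 1 − 1e−12 before atanh (duplicated ROIs stay finite).
* Censoring is strict (`fd > threshold` censored); a frame exactly at the
  threshold survives. The inclusion boundary is inclusive (600.0 s counts).
* Eigenvalue floor 1e−8 in the correlation repair; repair tolerance 0.05
  max elementwise change before erroring.
* Both-constant sequences make the ICC undefined → error, as does a
  constant ROI series at the correlation stage (named in the message).
* Constant features inside the elastic net get scale 1 instead of 0 to
  avoid NaNs; they are never selected.
* JN quadratics with |A| below machine precision fall back to the linear
  root; a zero interaction variance errors.
* All stage seeds derive from one master seed; the fold partition, the
  permutation stream, and the cohort are independently seeded so changing
  the permutation count does not perturb the fit.

## Known limitations

* The generator's frames are temporally independent; effective degrees of
  freedom in real BOLD are far lower at equal T, so absolute ICC magnitudes
  here are optimistic for equal scan lengths.
* The permutation null recomputes cell means per iteration from the full
  edge set; at real-data scale (tens of thousands of edges, thousands of
  subjects, 500 iterations) a chunked or parallel variant would be wanted;
  the interface accepts a worker-free loop only.
* No CIFTI/NIfTI ingestion: the file interface is parcellated TSV. Converting
  ptseries exports to TSV is assumed upstream.
* Familial nesting, multilevel site models, and alternative similarity
  indices (cosine, CKA, topological comparisons) are out of scope.
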