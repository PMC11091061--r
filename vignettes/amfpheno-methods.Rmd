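---
title: "Methods: hierarchical analysis of AMF colonization phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical analysis of AMF colonization phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfpheno)
```

# The scientific setting

Arbuscular mycorrhizal fungi (AMF) colonize plant roots and differentiate
into structures with distinct functions: arbuscules (nutrient transfer),
intraradical and extraradical hyphae (growth inside and outside the root),
vesicles (storage) and spores (reproduction). Instance-segmentation models
turn stained root images into per-structure records — class label, pixel
area, classifier confidence — at a throughput no human scorer can match.
`amfpheno` is the analysis layer above such output: it turns instance
records into slide-level colonization phenotypes and asks, with
hierarchical linear models, how colonization varies between plants and
between root depths, and which structure traits predict it.

# Phenotypes

For each slide (one root sample) and each AMF class $c$, with $R$ the total
root pixels on the slide:

* count density $= n_c / R$ (instances per root pixel),
* average class size $= p_c / n_c$ (pixels per instance; undefined and
  propagated as `NA` when $n_c = 0$),
* percent colonization $= p_c / R$ (dimensionless),

where $n_c$ and $p_c$ are the instance count and summed pixel area of class
$c$ after discarding predictions below the confidence threshold (default
0.7, the usual inference threshold for this kind of segmentation model).
Totals sum the five AMF classes; the `other` (non-AM) class never enters
totals. The derived allocation phenotype is the proportion of
nutrient-exchange structures,
$\mathrm{PNE} = (n_{arb} + n_{exH}) / \sum_c n_c$, a count-based measure in
$[0,1]$. Which classes count as "nutrient exchange" and which enter the
totals are arguments, not constants, because analyses occasionally drop
poorly segmented classes (intraradical hyphae being the usual casualty);
the defaults match the conventions above.

Proportion-valued phenotypes can be transformed with
`phenotype_transform()` (logit with an optional offset, or
arcsine-square-root). The logit offset defaults to 0: silently smoothing
exact zeros and ones hides data problems, so callers clip explicitly.
Count density is kept in raw count-per-root-pixel units; displays are free
to scale (published tables use a $10^9$ multiplier), and every derived
diagnostic below is invariant to that scaling.

# The model ladder

Root samples $j$ are nested in plants $i$: three root regions (TOP, MID,
BOT) times three replicates per plant. The working model is

$$y_{ij} = \beta_0 + \beta_{TOP}\,[region_{ij}{=}TOP] +
\beta_{BOT}\,[region_{ij}{=}BOT] + \textstyle\sum_k \beta_k x_{kij} +
u_{0i} + u_{1i} x_{1ij} + \varepsilon_{ij},$$

with $(u_{0i}, u_{1i})$ jointly normal (variances $\sigma^2_{u0}$,
$\sigma^2_{u1}$, covariance $\sigma_{u0u1}$) and
$\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)$, independent across
samples. Region enters as treatment dummies against the MID reference, so
the intercept is the MID mean; structure covariates are z-scored once on
the analysis dataset before any fitting, so coefficients are per-SD effects
and shared across the ladder. The ladder is the nested sequence null →
+region → +covariates → +one random slope, fitted by `build_model_ladder()`.

Assumptions worth keeping in mind: plants and samples are random draws from
their populations, random effects and errors are Gaussian with constant
variance, and the mean–variance relationship of the response is flat
enough after transformation. At most one random slope is supported; richer
random structures are not identifiable at 12 plants and were not needed in
the motivating analyses.

## Estimation

Likelihood maximization is delegated to `lme4` — the reference
implementation of REML/ML for linear mixed models — behind the `amf_mlm()`
surface; nothing would be gained by reimplementing the profiled deviance.
Two conventions are fixed here rather than inherited:

* **REML for variance components, ML for comparisons.** Reported variance
  components come from REML fits; deviance, AIC, BIC and likelihood-ratio
  tests always use ML (re)fits, because REML likelihoods are not comparable
  across fixed-effect structures. `likelihood_ratio_test()` refits
  automatically.
* **Parameter count** $k$ = number of fixed effects + number of distinct
  variance–covariance parameters (2 for a random intercept model, 4 with a
  slope). Then deviance $= -2\ell$, AIC $=$ deviance $+ 2k$, BIC $=$
  deviance $+ k\log n$. This convention reproduces the AIC/deviance gaps of
  the published ladders exactly.

Negative variance solutions are truncated at zero by the constrained
optimizer; fits flag singularity. On balanced one-way data the REML
solution has a closed form — $\hat\sigma^2_\varepsilon = MSW$,
$\hat\sigma^2_{u0} = (MSB - MSW)/J$ when $MSB \ge MSW$ — which the test
suite uses as an independent oracle. One subtlety the closed form must
respect: when $MSB < MSW$ the boundary solution collapses to the iid model
and the REML residual variance becomes $SS_{tot}/(n-1)$, **not** MSW; the
oracle in the tests implements this boundary case, and `lme4` agrees with
it to near machine precision.

## Variance-partition diagnostics

* `icc()`: $\sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_\varepsilon)$ — the
  between-plant share of total variance.
* `pcv()`: $(v_{ref} - v_{new})/v_{ref}$ per level against the null model;
  negative values are meaningful (a component can grow when a covariate is
  added).
* `vpc_at()`: with a random slope the plant-level variance is the quadratic
  $\sigma^2_{u0} + \sigma^2_{u1}x^2 + 2\sigma_{u0u1}x$, and the variance
  partition coefficient evaluates its share at any covariate value $x$;
  with no slope it reduces to the ICC for every $x$.
* `r_squared()`: marginal $= v_{fix}/(v_{fix}+v_{ran}+\sigma^2_\varepsilon)$
  and conditional $= (v_{fix}+v_{ran})/(\cdot)$, where $v_{fix}$ is the
  empirical variance of the fixed-effect predictor over the observations
  and, for slope models, $v_{ran}$ is the observation-averaged quadratic
  $\sigma^2_{u0} + \sigma^2_{u1}\overline{x^2} + 2\sigma_{u0u1}\bar{x}$.
  The ladder reports the same observation-averaged quantity as the "VPC"
  of a slope model, keeping one number per model comparable down the
  ladder; `vpc_at()` exposes the full curve.

# Selection workflow

Lasso screening (`lasso_screen()`) runs on the pooled, standardized data —
a deliberate simplification: the penalty is a screening device, the mixed
model is the inferential stage. The penalty is chosen by k-fold
cross-validation (seeded fold assignment, 10 folds) with the 1-SE rule,
via `glmnet`. Forward selection (`forward_select()`) then adds candidates
greedily by smallest LRT p-value below $\alpha = 0.05$;
`random_slope_search()` compares random-intercept against
intercept-plus-slope models per candidate (2 df) and retains at most the
single best slope. Two calibration facts shaped the defaults of the
validation suite: the one-df fixed-effect LRT against $\chi^2_1$ is
slightly anti-conservative at 12 plants (measured type-I error ≈ 0.04–0.06
at $\alpha = 0.05$, inside the acceptable band, converging with more
plants), and a *null* fixed effect whose slope still varies between plants
(an unmodeled random slope) inflates the fixed-effect test — so null
simulations for selection procedures must set the slope variance to zero,
and the forward-selection null check runs at 48 plants where the
$\chi^2$ reference is accurate.

Region contrasts (`region_contrasts()`) are pairwise mean differences
MID−TOP, MID−BOT, TOP−BOT on the one-way layout pooling plants, with
p-values from the studentized-range distribution (`ptukey`); a
plant-blocked variant (`block =`) removes the plant stratum from the error
term, since the published procedure does not state which layout was used.
`rank_compare()` is midrank Spearman correlation with the t-approximation
p-value.

# Annotation geometry

No polygon-clipping library is assumed; the geometric primitives are part
of the package and are deliberately simple and oracle-checkable:

* **Coordinates** are 0-based pixels; a pixel is covered when its center
  $(i+0.5, j+0.5)$ lies strictly inside the polygon interior.
* **Interior rule** is even-odd, which is deterministic for
  self-intersecting input.
* **Repair** (`repair_polygon()`) decomposes the even-odd interior by a
  scanline into trapezoid bands (band breaks at every vertex and every
  edge–edge intersection) and merges bands sharing an identical horizontal
  edge back into maximal simple polygons — a bowtie becomes exactly its two
  triangles. Output pieces are simple, pairwise interior-disjoint, and
  conserve the even-odd area to $10^{-6}$ relative.
* **Clipping** to a tile reuses the same decomposition restricted to the
  box, with extra band breaks where edges cross the vertical box sides so
  clamping stays exact; multi-part intersections come back as separate
  polygons, and point/segment degeneracies are discarded. A polygon
  entirely inside a tile is returned verbatim.
* **Tiling** (`tile_annotated_image()`) uses 512-px tiles by default,
  keeping smaller boundary tiles unpadded. Whether sub-100-px boundary
  tiles should be dropped is an open question in the source protocol (the
  100-px filter is stated only for prediction images); tiling therefore
  keeps all tiles by default and exposes `min_side`.
* **Rasterization** (`rasterized_area()`) is an even-odd scanline over
  pixel-center rows; the test suite checks it pixel-for-pixel against a
  brute-force point-in-polygon oracle. Pixel centers exactly on an edge
  are excluded by the strict-interior convention; test fixtures use
  vertices in general position, where such ties have probability zero.

The parser (`parse_annotations()`) applies the cleaning rules of the
source protocol: polygons kept, polylines closed, circles resampled as
64-gons (area error < 0.1%), point/rect/ellipse shapes and empty
segmentations removed, class vocabulary normalized with unknown labels
merged into `other` under a warning, vertices clamped to the frame, and —
because clamping itself can create self-intersections — every polygon
repaired on the way in.

# Segmentation evaluation

`average_precision()` follows the COCO conventions: predictions sorted by
descending confidence (ties broken by input order, recorded as such),
greedy one-to-one matching to the unmatched same-class, same-image truth
with highest IoU at or above the threshold, 101-point interpolated AP on
the 0–100 scale (exact all-point integration behind
`interpolation = "exact"`), AP averaged over IoU 0.50:0.05:0.95, AP50 at
0.5 alone. Cross-class matches never count. `evaluate_segmentation()`
averages mAP over classes with at least one ground-truth instance — the
defensible reading of a class-wise table in which every class, including
non-AM, has its own AP — and takes an explicit class list for any other
convention. Fisher's exact test on the predicted-vs-human class frequency
table enumerates when feasible and falls back to a seeded Monte-Carlo
approximation, reporting which path was taken.

# The synthetic-data generators

The generators exist so that every stage — including failure modes — runs
and is testable without any image download. They are pure functions of
parameters and seed.

`simulate_mlm_dataset()` draws from the two-level model itself. Its
defaults are the study conditions of the motivating experiment: 12 plants
× 3 regions × 3 replicates; fixed effects 0.3410 (intercept), 0.0226
(TOP), −0.0087 (BOT), 0.0937 (scaled arbuscule count) and 0.0304 (scaled
arbuscule size); intercept variance 9×10⁻⁴ and residual variance 7×10⁻⁴.
No published value exists for the slope variance, so its default (4×10⁻⁴)
is a synthetic-only choice set large enough that the plant-level variance
visibly grows with arbuscule count; it must not be read as an estimate.
Covariates are standard normal, matching their post-scaling distribution.

`simulate_instance_tables()` emulates segmentation output at slide
granularity: per-slide class counts are Poisson with a Gaussian copula
imposing the observed sign structure (arbuscule–extraradical hypha counts
positively correlated; vesicle–spore counts positively correlated;
vesicle/spore-rich slides having smaller arbuscules via a latent size
factor), instance areas are log-normal per class, one root instance
carries the root pixel budget, and confidences are left-skewed Beta draws
(root most confident). Region effects multiply arbuscule/extraradical
intensities and shift arbuscule size so TOP > MID > BOT, and plant-level
random effects on the log count intensity and on arbuscule size create the
between-plant clustering (nonzero ICC) that the hierarchical models are
there to partition. The per-class magnitudes (mean counts 8/5/4/4/3, sizes
150–400 px, root budget 2×10⁴ px, chosen so a typical slide shows ~30%
total colonization) are order-of-magnitude choices: realistic in scale,
but not estimates of any real dataset, and analyses of real data should
never take them as priors.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: spatial structure within images (instances
are exchangeable records, not placed masks), per-image heterogeneity
within a slide (the 4-fields-×-48-positions layout is collapsed to slide
granularity, which is the level at which all phenotypes are defined),
segmentation errors correlated with structure morphology, and the
plant-level coupling between total colonization and PNE reported in the
original study (the copula acts within slides; the plant intensity effect
multiplies all classes equally, leaving PNE uninformative about a plant's
total colonization by construction).

`simulate_mask_pairs()` builds evaluation fixtures with exact bookkeeping:
truth shapes (rectangles, ellipses, thin filaments emulating hyphae) on a
grid with margins wider than twice the prediction jitter, so a jittered
prediction can only overlap its source truth and TP/FP/FN at any IoU
threshold follow from the recorded per-prediction IoUs. The test suite
checks the evaluator's greedy matching against this bookkeeping on 100
seeded cases.

# Validation suite and problem sizes

The suite validates: geometry against brute-force rasterization oracles
(random star polygons, random crossed quadrilaterals, a pentagram whose
doubly-wound center the even-odd rule excludes); tiling area conservation
at $10^{-6}$ relative on batches of 100 random annotated images; the
balanced-REML closed form on 50 seeded 12×9 designs at $10^{-6}$ relative;
parameter recovery under the generating model at 24/96/384 plants (100
replicates each — variance-component RMSE shrinks monotonically, and ±2 SE
intervals cover the true fixed effects in ≥ 90% of replicates at 96
plants); type-I error of the one-df LRT within [0.03, 0.07] over 1000
null simulations; the average-precision toy case (one truth, one IoU-0.8
and one IoU-0 prediction: AP50 = 100, AP = 70) against a brute-force PR
enumeration; and the Fisher Monte-Carlo path against exact enumeration.
These sizes keep the whole suite under a few minutes on one CPU while
leaving every Monte-Carlo margin wide.

# Known limitations

* Gaussian responses only; proportions near 0/1 need transformation, and
  no generalized (e.g. binomial) mixed model is provided.
* One random slope at most; no crossed random effects.
* The lasso screening ignores the grouping structure by design; with few
  plants and strong clustering its selections should be read as a shortlist
  for the mixed-model stage, not as inference.
* Tukey contrasts assume the one-way (or randomized-block) layout and
  equal-variance normal errors.
* The geometric primitives target annotation-scale polygons (tens of
  vertices); they are exact but not engineered for millions of vertices.
* Published tables can be recomputed from their printed components
  (`recompute_reference_ladder()`) only up to the rounding of those
  components; refitting the original models requires the study's
  morphometric data, which is not redistributable here.
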