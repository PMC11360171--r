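---
title: "Predicting endocrine-disruption activity from expression signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting endocrine-disruption activity from expression signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgexar)
```

## The problem

Quantitative structure–activity relationship (QSAR) models predict a
chemical's toxicity from its structure, assuming structurally similar
chemicals act alike. That assumption breaks down when structurally unrelated
chemicals perturb the same biological pathway. `qgexar` implements the
complementary idea — a *qualitative gene-expression activity relationship* —
for endocrine-disruption endpoints: classify a chemical as active or
inactive against the estrogen receptor (ER binding), androgen receptor
(AR binding) or thyroid hormone receptor (TR antagonism) from the
differential gene-expression signature it induces in cultured cells.

The data model mirrors L1000-style profiling. A chemical treatment in one
cell line yields a z-score per gene (positive = up-regulation relative to
controls). 978 *landmark* genes are measured directly; the rest of the
transcriptome is imputed, split into *best-inferred* genes
(gene-level recall > 0.95) and lower-confidence *inferred* genes. Each
profile also carries a transcriptional activity score (TAS) summarising its
overall strength. Two cell lines (MCF7 breast carcinoma and A549 lung
carcinoma) observe each chemical from different cellular contexts, and the
final call combines both.

## Pipeline overview

1. **Assembly.** Activity records are collapsed to one per
   (chemical, endpoint); when literature sources contradict one another the
   chemical is considered active, and `n_sources` keeps the evidence count.
   When a chemical owns several expression profiles, the one with maximal
   TAS is retained (ties: first in input order, for determinism). Modelling
   uses landmark genes only by default; low-recall inferred genes are
   dropped.
2. **Split.** A validation set is drawn once, by simple random sampling,
   from the chemicals present in *both* cell lines, so the same held-out
   chemicals score each cell-line model and their consensus. Sampling is not
   stratified by class — the draw is an unbiased sample of the shared
   chemical space and the realized validation class balance is reported
   rather than controlled. Each cell line trains on its remaining chemicals.
3. **Feature selection.** MultiSURF weights (below), keeping features with
   weight strictly greater than 0, fit on training data only — inside every
   cross-validation fold the selector sees only that fold's training part.
4. **Models.** A class-weighted zoo — gradient boosting, random forest,
   linear SVM, elastic-net logistic regression, and a small feed-forward
   network — tuned by an inner 5-fold grid search and assessed by an outer
   10×5-fold repeated cross-validation, both scored by balanced accuracy
   (BA), which is robust to the pronounced inactive-majority imbalance.
5. **Consensus.** The two cell-line models' predicted probabilities are
   averaged; a mean of at least 0.5 is called active.
6. **Applicability domain.** A query is in-domain when its mean cosine
   similarity to its 3 nearest training profiles reaches
   `Dc = <y> − Z·σ`.
7. **Importance.** Per-gene Kruskal–Wallis tests between active and
   inactive chemicals, with raw p < 0.05 counted as significant.

`run_all()` executes the whole protocol from one `run_config()`; every
artifact TSV records the hash of the configuration that produced it, and one
global seed fans out to per-stage seeds by stable hashing of stage labels so
any stage reruns identically on its own. This package's interface is the R
functions plus this configuration object; the pipeline is meant to be driven
from R scripts rather than a shell, so no separate command-line binary is
shipped.

## MultiSURF

For target instance *i*, let `d_ij` be the Manhattan distance to instance
*j* computed on range-normalized features. The neighbourhood threshold is
`T_i = mean_j d_ij`, and a dead band `D_i = sd_j(d_ij)/2` excludes
ambiguous instances: *j* is a *near neighbour* when `d_ij < T_i − D_i`.
For each near neighbour, every feature's weight is decreased by the
normalized value difference if the neighbour shares *i*'s class (a hit) and
increased if it does not (a miss), with miss contributions scaled by
`P(class_j) / (1 − P(class_i))`; per-instance hit and miss contributions are
averaged within their groups, and the final weight averages over instances.
Features with positive weight discriminate the classes in their local
neighbourhood structure; selection keeps exactly those.

Three conventions are deliberate choices where the algorithm family admits
variants, following the published MultiSURF literature for continuous
features: Manhattan distance on range-normalized values, a dead band of half
the distance standard deviation, and near-neighbour updates only (no
far-neighbour term, which would be the starred variant). The implementation
is vectorized per target instance; the test suite pins it to an exhaustive
double-loop reference at `1e-10` on random instances, and to planted-gene
recovery at signal strengths where recovery should be near-certain.

A constant feature has weight exactly 0 and is never selected. If *every*
weight is non-positive the selection is empty; cross-validation loops then
fall back to the full feature set rather than fitting on zero columns —
relevant only for null-like data, where no selection is defensible anyway.

## The evaluation metrics

From confusion counts (active called at probability ≥ 0.5; the threshold and
the tie direction are package conventions, fixed once):

- sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
- balanced accuracy `BA = (SE+SP)/2`,
- `MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
- AUC via the Mann–Whitney rank statistic (midranks for ties), which equals
  the trapezoidal area under the ROC curve.

Degenerate cases follow two distinct conventions: SE or SP with an empty
class is *undefined* and reported `NA`; MCC with a vanishing denominator
factor is defined as 0 (the no-information value). Cross-validation
aggregation reports the arithmetic mean and sample SD per metric, with SD 0
for a single fold.

`reconstruct_confusion()` inverts rounded, published sensitivity/specificity
pairs back to integer confusion counts given the evaluation-set class
composition; the test suite uses it to verify that the package's formulas
reproduce published BA and MCC values to ±0.001. That exercise also settles
an ambiguity in the MCC formula as sometimes printed with a repeated
`(TN+FP)` factor: only the standard denominator reproduces the published
MCC values, so the standard form is implemented.

## Consensus

With two models, "majority vote" is undefined at disagreements, so the
consensus is the mean predicted probability, called active at ≥ 0.5. The
mean lies between the two inputs and is symmetric in cell-line order. When
the two models err confidently on disjoint chemicals while agreeing
elsewhere, averaging corrects both error sets — the mechanism by which the
consensus can beat either single model, demonstrated in the test suite by
construction.

## Applicability domain

Reliability is judged by neighbourhood density in signature space: the mean
cosine similarity of a query to its 3 nearest training profiles, computed on
landmark plus best-inferred genes (the AD describes the data manifold, not
the fitted model, so it uses the fuller reliable catalog even when the
classifier used selected landmarks; this is configurable). The threshold is
`Dc = <y> − Z·σ` with default `Z = 0.5`, where `<y>` and `σ` are the mean
and SD of the training chemicals' own leave-self-out mean top-3
similarities. Self-exclusion matters: including each chemical's
self-similarity of 1 would bias `<y>` upward and shrink the domain.
Because cosine similarity *increases* with proximity, the threshold
subtracts `Z·σ` where a distance-based rule would add it. Signed z-score
profiles can have negative cosine similarity; values are not clamped, and
thresholds in `[0, 1]` simply exclude them. `coverage_curve()` traces the
performance/coverage compromise: as the similarity threshold rises, coverage
is non-increasing and metrics are flagged `NA` once a retained class
empties.

## Gene importance

Kruskal–Wallis (rank-based, tie-corrected, chi-square with 1 df for the
two-group case — equivalent to a squared standardized rank-sum statistic) is
used instead of a t-test because z-score signatures are not normally
distributed. **No multiple-testing correction is applied**: the significant
count at raw p < 0.05 is a descriptive tally, so roughly 5% of genes pass by
chance under the null — the null-calibration test checks exactly this. A
direction annotation (sign of the median difference) distinguishes genes
over- from under-expressed in active chemicals.
`selection_capture_rate()` reports what fraction of the MultiSURF selection
is backed by this univariate evidence.

## The synthetic cohort generator

Real signature cohorts require controlled-access downloads, so every stage
is exercised on seeded synthetic cohorts with known ground truth. The
generator emulates: an L1000-like tiered gene catalog; z-score-distributed
features (background standard normal); cell-line divergence as an additive
per-(gene, cell line) offset drawn `Normal(0, cell_line_offset_sd)`;
a planted set of informative genes shifted by `effect_shift` in active
chemicals; inferred-tier genes with doubled noise SD (so landmark-only
models outperform all-gene models, as observed on real data); TAS drawn
uniformly and independently of the label (it only serves as a deduplication
key); class imbalance at a configurable prevalence; and optional duplicate
profiles and conflicting activity records to exercise the assembly rules.

Chosen defaults, fixed once: prevalence `484/1552 ≈ 0.312`, the ER-cohort
class balance in MCF7; `effect_shift = 2` z-score units and
`cell_line_offset_sd = 0.5`, values at which planted signal is clearly
recoverable but not trivial; 20 informative genes, all planted in the
landmark tier. No effect-size or noise statistics of real signatures are
published, so these are plausibility choices, not calibrations — which is
the central caveat on what the tests show. Passing parameter-recovery and
calibration tests demonstrates that the pipeline's machinery is correct and
unbiased under its own assumptions (independent Gaussian features, additive
shifts, label-independent TAS); it does not demonstrate predictive power on
real signatures, whose correlation structure, batch effects and
dose/time dependence the generator deliberately does not model.

## Problem sizes and numerical choices

The test and acceptance runs use scaled-down cohorts chosen as the package's
own working sizes: 300 chemicals × 200 genes for parameter recovery
(25 replicates), 300 × 1000 for null calibration of the significant-gene
fraction, 200 × 40 with 2×5-fold outer CV for null model calibration, and
300 × 60 with an 80-chemical shared validation set for the end-to-end
separable-cohort run. At these sizes the full suite runs in well under a
minute of CV work while leaving the statistical conclusions
(recovery ≥ 90%, null BA within 0.5 ± 0.08, ~5% null significance) stable
across seeds.

Numerical conventions collected in one place: probability ≥ 0.5 is active
everywhere a call is made; TAS ties keep the first profile; inner grid
search and best-model selection break ties by declared order; `which.max`
semantics make all tie-breaking deterministic; stratified folds guarantee
both classes in every fold and raise an error when `k` exceeds a class
count; conflict resolution sums pre-existing `n_sources` so re-resolving a
resolved table is the identity.

## Known limitations

- The feed-forward family is a single-hidden-layer perceptron; deeper
  architectures and AutoML searches are represented only through the
  `external` model interface, which accepts arbitrary fit/predict pairs.
- Default hyperparameter grids are small, pragmatic defaults, not tuned
  reproductions of any published grid.
- Probabilities are used as-is (no calibration); the linear-SVM
  probabilities come from Platt scaling and can be coarse on small folds.
- The generator draws genes independently; real co-expression makes feature
  selection harder than the synthetic tests suggest.
- The applicability domain is a single global threshold; per-class or
  density-based variants are out of scope.
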