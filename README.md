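# qgexar

Predicting chemical endocrine-disruption activity from gene-expression
signatures.

Chemicals that bind the estrogen receptor (ER), the androgen receptor (AR)
or antagonize the thyroid hormone receptor (TR) disrupt hormone-mediated
homeostasis. QSAR models screen for such chemicals from structure alone;
`qgexar` implements the complementary *qualitative gene-expression activity
relationship* approach: classify a chemical as active or inactive from the
differential expression z-score signature it induces in two cell lines
(MCF7 and A549), on an L1000-style gene catalog of 978 directly measured
landmark genes plus statistically imputed tiers.

The pipeline, end to end:

- **Assembly** — conflicting activity records resolve to *active*; duplicate
  profiles keep the highest transcriptional activity score (TAS);
  low-recall inferred genes are dropped; a shared validation set is sampled
  from the chemicals present in both cell lines.
- **MultiSURF feature selection** — relief-based weights with a
  mean-pairwise-distance neighbourhood threshold `T` and a dead-band zone;
  features scoring `> 0` are retained, fit on training folds only.
- **Class-weighted model zoo** — gradient boosting, random forest, linear
  SVM, elastic-net logistic regression, a small dense network, plus a
  plug-in interface; inner 5-fold grid search and outer 10×5-fold repeated
  cross-validation, both scored by balanced accuracy
  `BA = (SE + SP)/2`, with `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and AUC.
- **Consensus** — the mean of the two cell-line probabilities, active at
  ≥ 0.5.
- **Applicability domain** — mean cosine similarity to the 3 nearest
  training signatures against `Dc = ⟨y⟩ − Z·σ` (default `Z = 0.5`), with
  coverage/performance curves.
- **Gene importance** — per-gene Kruskal–Wallis tests between active and
  inactive chemicals, counting raw `p < 0.05`.

A seeded synthetic-cohort generator with planted informative genes and
known ground truth stands in for the controlled-access signature downloads,
so every stage is testable offline. See the methods vignette
(`vignettes/qgexar-methods.Rmd`) for the model assumptions and design
decisions.

## Worked example

```r
library(qgexar)

cfg <- run_config(
  cohort = list(n_chemicals = 200, n_landmark = 100, n_informative = 10,
                effect_shift = 1, seed = 42),
  models = list(
    random_forest = model_spec("random_forest",
                               grid = list(num_trees = 200L, min_node_size = 1L)),
    logistic_elasticnet = model_spec("logistic_elasticnet",
                                     grid = list(alpha = 0.5, lambda = 0.05))),
  repeats = 2, folds = 5, inner_folds = 3, n_validation = 50,
  seed = 7, out_dir = "demo_run")
res <- run_all(cfg)
```

The run simulates a 200-chemical two-cell-line cohort (100 landmark genes,
10 of them shifted by 1 z-score unit in actives), cross-validates both
models per cell line, refits the winner and scores the 50 shared validation
chemicals:

```
MCF7 best: logistic_elasticnet
  CV  <cv_report> logistic_elasticnet: 10 folds; BA = 0.926 +/- 0.033
  validation <metric_set> SE=1.000 SP=0.941 BA=0.971 MCC=0.915 AUC=0.998
A549 best: logistic_elasticnet
  CV  <cv_report> logistic_elasticnet: 10 folds; BA = 0.902 +/- 0.038
  validation <metric_set> SE=1.000 SP=0.882 BA=0.941 MCC=0.840 AUC=0.994
consensus <metric_set> SE=1.000 SP=1.000 BA=1.000 MCC=1.000 AUC=1.000
AD: Dc = 0.405 ; coverage = 0.76
```

Each cell-line model misclassifies a few inactive validation chemicals
(SP 0.941 and 0.882), but their errors differ, so averaging the two
probability vectors corrects all of them: the consensus balanced accuracy
(1.000) exceeds both single models — the motivation for profiling each
chemical in more than one cell line. The applicability-domain threshold
`Dc` computed from the training signatures retains 76% of the validation
chemicals as in-domain. `demo_run/` holds every artifact as TSV
(cross-validation reports, feature weights, validation predictions,
consensus table, AD assessments, importance tables) plus a JSON manifest
recording the config hash and seeds.

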