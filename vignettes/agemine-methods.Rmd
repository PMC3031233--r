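---
title: "Methods: classifying DNA repair genes as ageing-related"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying DNA repair genes as ageing-related}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemine)
```

`agemine` implements an interpretable classification pipeline for
distinguishing ageing-related from non-ageing-related DNA repair genes.
This vignette is the package's account of the science: the feature
construction, the two classifiers, the evaluation and significance
machinery, the synthetic-data generator, and the design decisions taken
where the procedure was genuinely open.

## Feature construction

### GO ancestor closure

Gene annotation databases record only a gene's most *specific* GO terms.
The ontology's semantics, however, imply every ancestor term along the
`is_a` hierarchy: a gene annotated to a specific biological process also
performs all of its generalisations. Leaving the ancestors implicit
makes term frequencies — and hence every probability a classifier
estimates from them — wrong. `close_annotation()` therefore extends each
gene's specific term set with all `is_a` ancestors before any column is
built, and restricts the result to the `biological_process` namespace
(the only namespace whose terms read naturally as predictors of
ageing-relatedness).

Three choices fix the closure's semantics:

* only `is_a` edges are followed; `part_of` and other relation types are
  out of scope,
* ancestor sets are *proper* (a term is not its own ancestor); the
  closed annotation re-unions the specific terms,
* the namespace filter is applied *after* closure, so a
  biological-process term whose ancestry crosses into another namespace
  keeps its biological-process ancestors only,
* annotation terms unknown to the loaded ontology are skipped with a
  warning rather than failing the build — ontology releases drift, and a
  stale annotation should cost one column, not the run. The package
  accepts any OBO release; run artefacts record the inputs used.

Each closed term becomes one binary `yes`/`no` column. Terms annotated
to only one or two genes carry essentially no statistical support, so a
**GO term occurrence threshold** `t` (default 3; the studied grid is
3, 7, 11) removes columns with fewer than `t` yes values — the boundary
is inclusive. Raising `t` trades attribute availability against the
reliability of per-term statistics; the threshold is applied after
closure and **before** duplicate-instance removal, which makes column
survival independent of the PPI variant chosen (the ordering is not
dictated by the procedure's description; this choice is flagged for
sensitivity analysis).

### Protein–protein interaction attributes

Interaction edges are filtered before any counting: an edge is kept iff
at least one endpoint is a cohort gene *and* its evidence includes an
`in_vivo` or `in_vitro` tag — interactions supported only by
high-throughput screens are treated as too weak. Duplicate unordered
pairs are merged first, with evidence unioned, so that evidence recorded
on any line of a repeated pair counts, and edge multiplicity never
inflates counts. Two attribute families follow:

* `n_partners` — the number of *distinct* interaction partners of the
  gene's protein product. A self-interaction contributes the protein
  itself once (the procedure's description is silent; counting once
  avoids double-counting a single physical observation).
* BPI columns — for each of the `N` most frequent interactor proteins, a
  binary column `<protein>_interaction`. Frequency ties are broken
  lexicographically so dataset construction is reproducible. `N` is 10,
  20 or 30 for variants D3, D4, D5.

### Dataset variants and deduplication

All variants share the DNA repair `pathway` column (12 nominal
categories), the `ka_ki` evolutionary-rate column (numeric, missing for
genes without an orthologue measure — stored as missing, never imputed;
both learners tolerate missing values), and the GO block. D1 adds no PPI
attributes; D2 adds `n_partners`; D3–D5 add `n_partners` plus 10/20/30
BPI columns.

Genes similar enough to coincide on *every* attribute and the class are
redundant from a data-mining perspective; `deduplicate_instances()`
keeps the first of each such group. Attribute-identical instances with
*conflicting* classes are all retained (with a warning): they carry real
label information, and silently dropping either side would bias class
frequencies.

### Expression-only dataset

The expression table is probe-level: different array generations probe
the same gene with different probe sets, which must not be mixed
upstream. `build_expression_dataset()` pools them by taking, per gene
and anatomy category, the arithmetic mean over all of that gene's probe
values. A gene with no probe in a category gets a missing value. Values
stay on the raw scale — no log transform — so learned thresholds are
directly comparable to reported expression cut-points, which are on that
scale.

## Classifiers

### Naive Bayes

The model scores each class `k` by
`P(C_k) · P(A_1|C_k) · … · P(A_m|C_k)` under the usual conditional
independence assumption — a deliberate simplification that is robust on
cohorts of ~140 instances, where dependence-modelling Bayesian variants
would overfit. Parameters:

* priors are unsmoothed class relative frequencies,
* nominal/binary conditionals use pseudo-count smoothing
  `(count + s) / (class count + s·|domain|)` with `s = 1`, so an unseen
  value never zeroes a product,
* numeric attributes get per-class Gaussians. Standard deviations are
  floored at `sqrt(1e-6 × global variance)` (never below 1e-9): a
  within-class constant value must not produce an infinite density
  spike.

Prediction accumulates in log space and normalises; attributes missing
on the instance are skipped (the empty product leaves the priors), and a
nominal value unseen at training time is treated as missing with a
message. Log-space accumulation agrees with direct product evaluation to
well below 1e-9 on small fixtures; the suite asserts this.

### Decision tree

The tree learner follows the C4.5 family, whose published defaults fix
the internals that the procedure's description leaves open:

* **Split selection.** Every attribute proposes its best split — for
  numeric attributes a binary `≤ / >` cut at a midpoint between
  consecutive distinct observed values (the threshold maximising
  information gain; ties go to the smallest threshold), for
  nominal/binary attributes the multiway split over the full value
  domain. Among proposals whose gain reaches the *mean* gain of all
  proposals (the eligibility guard that stops the gain-ratio criterion
  from favouring near-trivial splits), the highest **gain ratio** wins;
  remaining ties go to attribute column order, for determinism.
* **Stopping.** Purity, attribute exhaustion, fewer than `2·min_leaf`
  instances, or no admissible split (at least two branches with
  `min_leaf = 2` instances). Single-class input yields a single leaf,
  not an error.
* **Missing values.** During both training and prediction an instance
  missing the tested value goes to the heavier branch (more training
  instances; ties to the first). Fractional instance weighting is a
  stated non-goal.
* **Pruning.** Pessimistic subtree replacement at confidence 0.25: a
  node is collapsed to a leaf when the confidence upper bound on the
  leaf's training error (the exact beta-quantile form,
  `qbeta(1 − CF, E + 1, N − E)`) does not exceed the sum of its
  children's bounds. By construction pruning never increases the
  estimated error; subtree raising and rule post-pruning are non-goals.
* **Leaf probabilities.** Laplace-corrected leaf proportions,
  `(n_pos + 1)/(n + 2)`. Whether the original analysis smoothed leaf
  probabilities for its AUC is unstated; the Laplace correction is the
  conventional choice for ranking with small leaves and is noted for
  sensitivity checks.

Training is fully deterministic given the dataset and parameters.

## Evaluation

Accuracy is the area under the ROC curve from stratified 10-fold
cross-validation. Folds are stratified by class — with only ~33
positives, unstratified folds can leave a test fold with one or zero
positives, destabilising the estimate — and the fold shuffle takes a
required, recorded seed. AUC uses the rank-sum (Mann–Whitney)
formulation with midrank tie correction: the probability that a random
positive outranks a random negative, ties counting one half. It is
computed **once on predictions pooled across the ten test folds** rather
than averaged per fold: a single AUC is reported per experiment, pooling
is the convention of the mainstream data-mining toolkits for binary
problems, and per-fold AUCs on 3–4 positives are too unstable to
average meaningfully. The positive class for ROC purposes is `ageing`.

## Rule analysis

Each root-to-leaf path is an IF-THEN rule; redundant numeric conditions
on one attribute collapse to the tightest interval. A rule covering `n`
instances, `k` of them in its predicted class, is scored with the exact
one-sided binomial tail `P(X ≥ k)` for `X ~ Binomial(n, p0)` — one-sided
because only *over*-representation of the ageing class is the question.
`p0` is the predicted class's relative frequency in the dataset the rule
is evaluated on, recomputed per dataset (about 0.23 for the attribute
cohorts and 0.22 for the expression cohort at the reference cohort
sizes; where an analysis leaves the choice ambiguous the report can
compute both). The tail is accumulated on the log scale via log-Gamma
binomial coefficients and matches brute-force summation to 1e-12 for
n ≤ 30. No multiple-testing correction is applied — matching the
original single-pattern usage — but the number of rules tested is
attached to every report so users can correct downstream. Instances
missing a tested value are excluded from both trials and successes.

## The synthetic-data generator

`generate_cohort()` produces complete inputs — ontology, annotations,
PPI edges, gene table, probe-level expression — with planted structure.
Its defaults *are* the study conditions: 140 genes, 33 positives (class
frequency 0.236, inside the 0.22–0.24 regime of the reference cohorts);
a ~150-term biological-process DAG of depth ≤ 8 whose closed annotations
give a sparse binary matrix; positives drawing markedly more interaction
partners (8 + Poisson(10), crossing the 15-partner neighbourhood that
separates the classes) than negatives (Poisson(5)); a hub gene whose 11
cohort partners are 10 positives and 1 negative; 108 anatomy categories
with one planted tissue (`T_lymphocyte`) whose positive-class expression
is upshifted ×3 on the lognormal location scale; and a deliberately
non-predictive Ka/Ki column (identical lognormal in both classes),
mirroring the finding that evolutionary rate carried little signal.
Expression baselines are lognormal with medians near 2000 on the raw
scale, so planted thresholds fall in the thousands — echoing the
magnitude of reported expression cut-points without claiming their
units.

Generation is **constructive**: labels are assigned first and every
attribute is drawn conditional on the label, so planted coverage counts
are realised exactly (the hub pattern is (11, 10) by wiring, not in
expectation), which is what lets the suite assert exact values for
`rule_coverage()` and `binomial_significance()`. The same seed yields
byte-identical emitted files. Decoy edges — high-throughput-only
evidence, and background–background pairs — exercise the interaction
filter.

What the generator does *not* emulate: the real GO's topology and term
co-annotation structure, the empirical PPI degree distribution and its
study biases (hubs are over-studied in the ageing literature), array
normalisation, and correlations between attribute families. Passing
tests therefore demonstrate that the pipeline recovers signal it is
known to contain under realistic shapes and noise — not that any
particular biological cohort contains such signal.

## Numerical choices and degenerate inputs

* Gains below 1e-12 are treated as zero; the mean-gain guard uses a
  1e-9 slack so borderline candidates are not excluded by rounding.
* Pruning comparisons use a 1e-9 slack in favour of the simpler tree.
* CSV cells render doubles with `%.17g`, which round-trips exactly;
  model JSON uses 17 significant digits for the same reason. Missing is
  `?` in both CSV and ARFF.
* Leaf class ties break towards the first class level
  (`non_ageing`), deterministically.
* Empty nominal branches become leaves predicting the parent majority.
* Single-class training data: an error for Naive Bayes and for dataset
  construction (a classification task needs both classes), but a single
  leaf for the tree (a legitimate degenerate model).
* AUC is an error when only one class is present among predictions.

## Problem sizes used by the test-suite and acceptance runs

Property-style tests run the generator at its defaults (140 genes) for
pipeline-level claims and at 40–80 genes for structural checks; oracle
comparisons use DAGs of ≤ 200 terms, datasets of ≤ 50 instances for
exhaustive split enumeration, and n ≤ 30 for binomial brute force.
Seed-robustness claims (root-attribute recovery, null-cohort AUC) use 20
seeds; the expression effect-size sweep uses 5 shift values × 4 seeds.
These sizes were chosen so every claim is checked at the study's own
scale or at the largest scale where the corresponding oracle is exact.

## Known limitations

* Nominal splits are always multiway; C4.5's optional binary grouping of
  nominal values is not implemented.
* Missing values route whole instances to the heavier branch; fractional
  weighting would use the evidence more efficiently.
* The binomial test treats rules as pre-specified; rules read off a
  fitted tree are selected on the same data, so their p-values are
  optimistic — the per-report rule count supports external correction,
  but no selective-inference adjustment is built in.
* Reproduction of any external cohort's exact AUC tables is out of
  scope: those depend on the cohort files and on unstated learner
  settings of the original toolkit.
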