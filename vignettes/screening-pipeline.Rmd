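---
title: "Predicting low-language outcomes from lexico-semantic network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting low-language outcomes from lexico-semantic network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexscreen)
```

## The problem

Developmental language disorder (DLD) affects roughly 7% of school-aged
children but is rarely identified before school entry, even though its roots
are visible in toddlerhood. Parent-report vocabulary checklists (of the
MacArthur-Bates CDI family) are cheap, validated and easy to administer, yet
simple linear models on vocabulary size have never reached clinically useful
sensitivity. `lexscreen` implements a screening pipeline that augments
vocabulary size with *graph-theoretic structure* of the child's productive
lexicon and feeds the result to cross-validated random-forest classifiers,
evaluated with the metric suite clinicians use for screening instruments
(sensitivity, specificity, balanced accuracy, predictive values, likelihood
ratios).

The package is organised as a pipeline over four inputs: a long-format
checklist (child, age, produced word), a semantic-feature lexicon (word to
feature set), a vocabulary-size norms table (age x raw score to percentile),
and a per-child table of grammar items, demographics and the binary
low-language (LL) outcome.

## The noun-feature network and its five measures

For each child at each checklist age, the produced nouns found in the feature
lexicon become nodes of an undirected graph; two nouns are linked when their
feature sets share at least `min_shared = 2` features. Words missing from the
lexicon still count toward raw vocabulary size but never enter the network.
From this graph we compute:

* **Mean path length (MPL)** — mean shortest-path distance over *connected*
  node pairs. Unreachable pairs are excluded rather than counted as
  infinite; a network with no connected pair reports 0 and a quality flag.
* **Global clustering coefficient (GCC)** — the mean of per-node local
  clustering coefficients, with nodes of degree < 2 contributing 0. The
  triangle/triple transitivity ratio is a different statistic (0.75 on the
  worked example below, against 0.83 for mean-local) and is available via
  `variant = "transitivity"`; mean-local is the default because it is the
  definition consistent with the worked value.
* **Mean degree (MD)** — 2|E|/n.
* **Mean betweenness centrality (meanBC)** — per node, the sum over
  unordered pairs of the fraction of shortest paths through it;
  unnormalized, endpoints excluded, each pair counted once, fractional
  credit shared across multiple shortest paths. A normalization switch
  (divide by (n-1)(n-2)/2) exists but is off by default: no printed value
  constrains the choice, and unnormalized values keep small networks
  comparable with the worked example.
* **Mean harmonic centrality (meanHC)** — per node, the sum of inverse
  distances to all other nodes divided by n-1, with unreachable nodes
  contributing 0. This is the standard harmonic definition: it is the only
  variant that both handles isolated nodes and lies in [0, 1], the two
  properties the measure is used for here (closeness, the inverse of the
  sum, has neither).

Empty and singleton networks return all-zero metrics with a quality flag
rather than `NA`, so the modeling layer always receives numbers; the flag is
carried into the feature table's metadata.

```{r example-network}
net <- example_network()
compute_all_metrics(net)
```

The four-noun fixture above is constructed so that its edge set is forced by
a small set of constraints (five edges, eye of degree 3, apple and balloon at
distance 2, one open and one closed triple); `example_lexicon()` realises it
as an actual feature lexicon whose two-shared-feature graph is exactly this
network.

## From records to the 14-predictor table

`assemble_features()` produces one row per (child, age-band) record with 14
predictors: the five network measures, the vocabulary-size percentile, two
early grammar items, and six demographic variables.

* **Vocabulary percentile** uses a step-function (floor) lookup in the norms
  table, on the raw count of *all* produced checklist words — percentile
  norms are defined over total productive vocabulary, not just nouns.
* **Word combining** is the checklist's single milestone item, scored
  0 for "Not Yet" and 1 for either "Sometimes" or "Often".
  **Grammatical complexity** is the count of endorsed morpho-syntactic
  items. Both may be missing; numeric missingness is imputed *within
  training folds only*, by the training-fold median, so no information
  crosses a validation boundary.
* **Demographics** (gender, race, family history of speech/language
  disorder, household income, maternal and paternal education) are
  categorical with an explicit `"missing"` level — missingness patterns are
  themselves informative and the models should see them. Forests consume
  the categories as integer codes; split-based learners need no dummy
  expansion.

Two age bands are modeled independently: younger (16- and 18-month
checklists) and older (27- and 28-month), matching the harmonization of the
two emulated cohorts. Children contributing records at both ages appear in
both bands; each band is treated as its own modeling dataset.

## The classifier protocol

`nested_cv_fit()` implements nested cross-validation with stratified folds:
an outer loop (3 folds, repeated) estimates generalization; everything that
could leak — SMOTE oversampling, feature ranking, pruning, mtry tuning —
happens in an inner loop (5 folds, repeated) run on the outer-training
partition only.

* **SMOTE.** With ~4% prevalence, forests would otherwise learn to say
  "typical" always. The minority class is oversampled to 1:1 by
  interpolating between a minority row and one of its k = 5 nearest
  minority neighbours (Euclidean distance over median/MAD-standardized
  numeric predictors); categorical fields are copied from the anchor row.
  Synthetic rows are convex combinations of real minority rows by
  construction. With a single minority row the method falls back to
  duplication, with a warning.
* **Drop-one importance.** A feature's importance is the percentage-point
  change in plain classification accuracy between the full forest and a
  forest retrained without that feature, evaluated on inner held-out folds
  and averaged. This is retraining importance as specified, not permutation
  importance; it is honest about redundancy (an exact duplicate column
  scores near zero because its twin compensates), which is why rankings
  need many repetitions to stabilise. Ties break alphabetically so results
  are reproducible.
* **Pruning and tuning.** The top 7 of 14 features are retained; mtry is
  tuned over 2..7 by inner-CV balanced accuracy (SMOTE-balanced folds make
  plain and balanced accuracy nearly equivalent, and balanced accuracy
  stays defined under residual imbalance), ties to the smaller value.
  Forests use 500 trees throughout; votes are thresholded at 0.5.
* **Scale.** Full-protocol defaults are 3x10 outer, 5x10 inner and 100
  training runs. The package's `desk_scale()` preset (5 runs, 3x2 outer,
  5x2 inner) is what the bundled analyses and tests use; the number of
  independent runs changes the precision of the per-run balanced-accuracy
  distribution, not its location. Unit tests use further-reduced shapes
  (single repeats, 100-tree forests) chosen so each test isolates one
  property.

`fit_final_model()` trains one deployable model on a whole dataset (same
inner selection protocol) for external validation; unseen factor levels in
the target dataset map to the `"missing"` level and numeric gaps use the
*training* medians. External validation retrains a single model on the full
source dataset rather than ensembling the CV models — the simplest reading
of train-on-A/test-on-B, recorded here as the package's choice.

Every fit is bit-reproducible given (seed, config): fold assignment, SMOTE,
forest growth and vote tie-breaking at prediction all draw from explicit
seeded streams, never from the session RNG.

## Evaluation

`screening_metrics()` derives the clinical suite from a pooled confusion
matrix. Degenerate denominators keep their clinical reading: specificity 1
gives LR+ = Inf (a positive call is certain evidence), specificity 0 gives
LR- = Inf, and an empty margin makes PPV/NPV missing, never 0. Per-run
balanced accuracies are tested against the 0.5 of a single-class classifier
with a one-sided one-sample t-test; constant accuracies are reported as
degenerate rather than silently producing a p-value. Report tables round
half-up at 2 decimals for display (so 0.99/0.18 prints 5.50) while
machine-readable output keeps full precision.

## The synthetic-data generator

No real cohort data ships with the package, so `generate_children()` creates
datasets with the structure the pipeline assumes. Two presets mirror the
study designs: `"eirli"` (391 children, 4.3% LL prevalence, checklist waves
at 16 and 28 months with 314 and 390 records) and `"laser"` (85 children,
14% prevalence, waves at 18 and 27 months, all children at both).

Mechanics, each on its own RNG stream derived from the master seed:

* a synthetic feature lexicon (160 nouns, 120 features, 2-4 features per
  word, Zipf-skewed feature frequencies) whose two-shared-feature graph has
  genuine hubs; 60 further non-noun checklist words carry no features;
* raw vocabulary sizes are lognormal per band (TD medians ~55 words at the
  younger ages, ~120 at the older, of a 220-word checklist — a deliberately
  scaled-down instrument, roughly one third of the real checklist's nouns,
  keeping per-child graphs small enough for thousands of model fits);
* the LL signal enters through three independent dials, and each LL child
  draws one *dominant mechanism* so the group is clinically heterogeneous
  rather than moving in lockstep: a vocabulary-size deficit
  (`ll_vocab_shift`, default -1.3 on the log scale; dominant-mechanism
  children get 1.6x of it — a "barely talking yet" profile — and all other
  LL children a mild 0.4x), hub-avoidance (`structure_bias`, default 3.5;
  affected children sample nouns with weight (1 + connectivity)^-bias,
  thinning their networks at any given size), and thematic sampling
  (`theme_bias`, default 60; affected children over-sample one random
  lexicon neighbourhood, producing a single dense cluster — high
  clustering/degree — with a sparse periphery). Distinct mechanisms give
  different measures genuinely distinct diagnostic work to do, which is
  what drop-one importance can reward; with a single mechanism all network
  measures would be near-copies and drop-one importance would credit none
  of them (its known redundancy blindness). Setting any dial to 0 removes
  that signal component; with all three at 0 the groups are exchangeable.
  Default magnitudes were calibrated once so that parameter-recovery runs
  sit near the performance band the method is known for (balanced accuracy
  ~0.85-0.95) without saturating; they are otherwise arbitrary and are not
  revisited;
* grammar items follow logistic/Poisson links from raw vocabulary size with
  deliberately shallow slopes — grammar tracks language level weakly, so
  the injected lexical signal remains the dominant one and the grammar
  items act as near-null competitors in feature selection; ~5% of grammar
  responses are missing;
* demographics are outcome-independent categorical draws with per-variable
  missingness (1-10%), i.e. pure noise features under the default
  configuration;
* the norms table is built from the empirical TD raw-score quantiles at
  each age (odd percentiles 1-99), which makes percentile lookup
  self-consistent: the TD median maps to the 50th percentile up to lookup
  granularity.

What the generator does *not* emulate: psycholinguistic structure of real
feature norms (licensed separately), longitudinal vocabulary growth within
child, demographic-outcome associations, and measurement error in the
outcome itself. Passing tests therefore demonstrate that the pipeline
recovers signal of the injected kind under realistic sizes and prevalences
— not that real checklists carry that signal.

`shuffle_labels()` permutes outcomes while preserving prevalence, providing
the null configuration under which the pipeline's out-of-fold balanced
accuracy should sit at 0.5.

## Numerical conventions and degenerate inputs

* Empty/singleton networks: all-zero metrics plus a quality flag.
* MPL of an edgeless network: 0 (flagged), never `NaN`.
* Percentile lookup below the smallest tabulated raw score returns that
  age's minimum percentile; above the largest, the maximum.
* Stratified folds deal each class round-robin after shuffling, so class
  counts per fold differ by at most one; a dataset whose minority count is
  below the outer fold count is rejected rather than silently unstratified.
* Importance ties break alphabetically; mtry ties break to the smaller
  value; classification threshold is fixed at 0.5.

## Known limitations

Drop-one retraining importance under-credits correlated predictor blocks
(each member of the block looks dispensable); rankings are reported with
selection frequencies across folds so this is visible. The external-validity
experiment is only as hard as the generator's cross-dataset differences —
real cohorts differ in outcome definition and ascertainment age in ways the
generator only caricatures via its dials. And the scaled-down checklist
means absolute metric values (e.g. mean degree) are not comparable to values
computed on the full instrument.
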