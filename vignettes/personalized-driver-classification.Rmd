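---
title: "Classifying personalized tumor suppressors and oncogenes from multi-omic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying personalized tumor suppressors and oncogenes from multi-omic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perDriveR)
```

## The problem

Cohort-level driver-gene methods need many samples carrying the same
alteration and therefore miss rare drivers, and they rarely say what a
driver *does*. perDriveR treats the question as supervised, per-patient
classification: every altered (sample, gene) pair is assigned one of
the classes NEUTRAL, TSG (tumor suppressor, loss-of-function driver) or
OG (oncogene, gain-of-function driver) — or DRIVER/NEUTRAL in the
binary variant. The classification unit is the pair, so a gene may be a
TSG in one patient and an OG in another, and a driver observed in a
single sample can still be called.

## Labeling: four strategies, no gold standard

There is no per-patient gold standard, so training labels come from
curated resources under four strategies:

* **mutation-exact** (`mutation_exact_binary`, `mutation_exact_tsg_og`):
  a pair is a driver only when one of its mutations matches a curated
  driver mutation on (gene, position, ref, alt). Driver-mutation rows
  are first filtered to evidence score strictly `> 15`
  (`evidenceThreshold`). A pair matching both a TSG- and an OG-labeled
  mutation is left unlabeled rather than resolved by precedence,
  consistent with excluding dual-role genes at the list level.
* **gene-level** (`gene_pan`, `gene_cancer_specific`): every altered
  pair (mutation or nonzero copy-number score) of a listed gene
  inherits the gene's role; tags `tsg`/`possible tsg` map to TSG and
  `oncogene`/`possible oncogene` to OG; genes carrying both role
  families are excluded before labeling.

Neutral-list genes are NEUTRAL under every strategy; everything else
remains UNLABELED and is reserved for prediction. The gene, not the
mutation, is the unit: one matching mutation labels the pair even if
its other mutations do not match.

## Features

**SNV block.** Mutation types are one-hot encoded over a fixed
vocabulary. Each annotation tool contributes a numeric score and a
categorical prediction; predictions become ordinals over the tool's
declared benign-to-damaging order with missing values at 0. Because
per-pair aggregation takes maxima, each tool's score is first oriented
so that larger means more damaging (declared per tool in the
configuration; SIFT-style scales, where low means damaging, are
flipped to `1 - s`).
Per pair the score and ordinal are the maxima over its mutations, the
one-hot type is the type of the mutation with the highest mean oriented
score (ties resolved by a fixed severity order, nonsense first), and
onco-domain bits are the union of the mutations' Pfam annotations
intersected with the cancer type's domain list. Two feature-set
policies exist: `"all"` keeps the score block and drops pairs any tool
could not score; `"small"` drops the scores and keeps every pair, so
`"small"` never has fewer rows — the reason to prefer it when missing
rates are high.

**RNA block.** Differential expression is computed per tumor sample
against the pooled normals. A single common negative-binomial
dispersion `phi` (BCV `= sqrt(phi)`) is estimated for the cohort by
profile likelihood: for a candidate `phi` each gene's per-condition
mean is set to its MLE under library-size offsets, and `phi` maximizes
the summed log-likelihood via a 1-D search on `log(phi)` over
[1e-6, 4] (tolerance 1e-4). Per sample and gene the features are
`logFC = log2((cpm_t + c) / (mean normal cpm + c))` with prior count
`c = 0.5` CPM, and `logCPM = log2(mean cpm + c)` over the tumor sample
and the normals. A two-sided NB tail p-value at the cohort dispersion
is exported for reference but never used as a feature. Network
features from the score-filtered interaction graph (edges kept iff
max(experimental, database) channel score is strictly above 700; the
graph is unweighted — scores gate existence only): degree,
Wasserman–Faust closeness (chosen because interaction subgraphs are
routinely disconnected), pair-normalized exact betweenness, the three
`logFC x centrality` products, and the neighborhood features over
1-hop neighbors (`hops` configurable): `neigh_FC`, the sum of logFC
over neighbors with `|logFC| > tau`, and `neigh_normFC`, that sum per
differentially expressed neighbor. `tau` defaults to 1.0 in log2 units
(fold change 2); the threshold is read as a fold-change threshold and
applied to `|logFC|`, resolving the two slightly different phrasings a
reader might use, and it is configurable.

**Multi-omic block.** The SNV and RNA blocks are joined on the altered
pair universe (mutated union CNV-nonzero pairs), plus the GISTIC-style
`cnv_score`, the CNV-conditioned neighborhood features
(`neigh_CNV_FC`, restricted to neighbors with nonzero copy number),
and the sample-level expression of the declared oncogenic miRNAs
(identical across genes of a sample; gene-specific miRNA interactions
are out of scope). CNV-only pairs are kept with `has_mutation = 0` and
an all-zero SNV block: the flag lets a tree distinguish "no mutation"
from "benign evidence", which the zero sentinel alone could not.

## Models

Class imbalance (neutral pairs dominate) is handled inside the
ensembles rather than by reweighting:

* **balanced bagging**: each tree trains on an independent balanced
  bootstrap — classes under-sampled to the minority count, drawn with
  replacement within class;
* **balanced random forest**: per-tree stratified balanced sampling
  (via `randomForest` with `strata`/`sampsize`);
* **easy ensemble**: boosted shallow trees (multi-class AdaBoost,
  SAMME weighting) on independent balanced under-samples.

Samples — not pairs — are split 70:30 into train and test, so pairs of
one sample never straddle the split; cross-validation folds inside
training are also assigned at the sample level (stricter than
pair-level folds, avoiding within-sample leakage). Grid search over
`{50, 100, 200}` estimators × tree depth `{unbounded, 10, 20}` selects
the best mean macro-F1 across 5 folds; macro-F1 is the tuning metric
because accuracy is dominated by the neutral class under imbalance. A
single-row grid skips the search. Metrics derive from the confusion
matrix; classes with zero support are reported as undefined (`NA`),
never 0. Rankings use the driver score `1 - P(NEUTRAL)`, treating TSG
and OG symmetrically; ties break lexicographically so output is
deterministic.

Two negative controls are built in: label permutation (training labels
shuffled, test untouched — per-class F1 should collapse) and network
randomization (node-label permutation destroying per-gene degrees, and
degree-preserving double-edge swaps destroying neighborhoods only).
The network control defaults to the RNA feature block, where half the
features derive from the graph, so it isolates the network's
contribution.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the classifier
exploits, with defaults fixed as the reference study conditions: 100
samples (80 tumor / 20 normal), 300 genes, 15 planted TSGs, 15 OGs, 60
neutral genes; true BCV 0.4; planted driver |logFC| 2.0 (TSGs down,
OGs up, in all tumor samples); oriented damaging scores
Uniform(0.7, 1) for drivers vs Uniform(0, 0.5) otherwise; 15% missing
scores. Values the reference conditions leave open were chosen once as
field-plausible and not revisited: mutation rates per tumor sample
0.35 / 0.15 / 0.05 for driver / neutral / background genes, CNV rates
0.35 / 0.12 / 0.08 with losses in TSGs and gains in OGs, a
preferential-attachment network (3 edges per node) with drivers
sampled toward hubs at moderate strength (`hubBias = 1`), driver
mutations recurrent at 3 hotspot positions per gene (rate 0.7) which
also form the mutation-level driver resource (evidence scores
Uniform(5, 40), so the `> 15` filter bites), a planted Pfam domain per
driver class (rate 0.6), and co-dysregulation of driver-adjacent genes
at |logFC| 1.5 (rate 0.8, sign following the majority of adjacent
drivers) so that neighborhood features carry real signal. Counts are
negative-binomial over log-normal baselines with library sizes
Uniform(0.5e6, 2e6).

What the generator does *not* emulate: real marginal distributions,
gene length bias, correlated mutational signatures, subclonality,
batch effects, or paired tumor-adjacent normals. Passing tests
therefore demonstrate internal correctness and recoverability of
planted signal, not performance on real cohorts.

A hand-checkable 6-gene, 3-sample micro-cohort ships as plain files
(`toyExampleDir()`) together with hand-enumerated expected label
tables for all four strategies; the test suite requires exact
agreement.

## Numerical choices and degenerate inputs

* Cutoffs from the labeling and filtering rules are strict
  inequalities (`> 700` interaction score, `> 15` evidence,
  `|logFC| > tau`); boundary values are excluded.
* MISSING is a typed sentinel (`NA`), distinct from 0; ordinals encode
  it as 0 by definition, scores never silently do.
* The dispersion search reports boundary solutions with a warning and
  returns the boundary value; all-zero genes are excluded; a gene
  absent from one condition contributes a zero MLE mean.
* Isolated network nodes have closeness 0 and empty neighborhoods;
  off-network genes get zero network features; samples without a DEG
  profile are dropped from feature assembly with a warning.
* Writers emit floats at 6 significant digits in a fixed column order,
  making outputs byte-identical across runs with equal inputs and
  seeds.

## Problem sizes used by the test suite

The acceptance-style checks run the default 100-sample cohort once and
share it across checks; parameter-recovery simulations use 2,000 genes
x 30 samples (dispersion) and 1,500 genes x 15 samples (fold-change
recovery); oracle equivalences use 50 random graphs of at most 15
nodes; unit tests use a reduced 40-sample, 120-gene cohort. These
sizes are the package's reference experiment sizes; the generator
scales beyond them if needed.

## Known limitations

* With gene-level labeling every pair of a gene shares one class, so a
  flexible learner can recover a gene's class from any
  gene-identifying feature (for example its characteristic abundance,
  `logCPM`). Held-out performance across samples therefore overstates
  generalization to unseen *genes*, and the marginal contribution of
  any single feature family — including the network block, as the
  randomization control shows — can be small under the generator's
  defaults. This mirrors the real setting, where evaluation is also
  dominated by genes seen in training.
* The single-sample expression model uses plain CPM normalization with
  a prior count and a common dispersion; no TMM, tagwise dispersion or
  FDR control is attempted, and agreement with any particular external
  DEG implementation is not a contract (the common-dispersion estimate
  is cross-checked against an independent qCML implementation in the
  tests, to a loose tolerance).
* Probabilities from balanced ensembles are not calibrated; the driver
  score supports ranking, not risk interpretation.

## A short session

```{r, eval = FALSE}
library(perDriveR)

cohort <- simulateCohort()                      # or readCohort(dir, config)
config <- synthDriverConfig(
  grid = data.frame(nEstimators = 50L, maxDepth = Inf, minBucket = 1L),
  seed = 11L)

pipe <- runPipeline(cohort, config,
                    strategy = "gene_cancer_specific", block = "multiomic")
pipe$evalTest                                   # held-out metrics
head(pipe$predictions)                          # per-pair classes + ranking
importanceConsensus(pipe$model)$top             # top contributing features
```
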