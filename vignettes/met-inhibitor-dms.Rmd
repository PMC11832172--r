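---
title: "Scoring and classifying inhibitor resistance in a MET kinase-domain deep mutational scan"
author: "metdms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying inhibitor resistance in a MET kinase-domain deep mutational scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdms)
suppressPackageStartupMessages(library(SummarizedExperiment))
```

## The experiment this package models

Pooled deep mutational scanning (DMS) of a kinase domain measures the
growth effect of (nearly) every single amino-acid substitution at once.
A saturation-mutagenesis library over MET kinase-domain residues
1059–1345 is expressed as a constitutively active TPR fusion in Ba/F3
cells, which survive IL-3 withdrawal only through MET kinase activity.
The pool is grown under each of 11 ATP-competitive MET inhibitors (at
equipotent dosing) plus a DMSO control; samples are harvested at T0 and
then every two wild-type doublings for three more time points, and each
sample is sequenced to count every variant. A variant that resists an
inhibitor keeps its cells proliferating while the sensitive background
dies out, so its read share rises over the time course.

The default `ExperimentDesign()` encodes that layout — 2 libraries ×
3 replicates × 12 conditions × (1 shared T0 + 3 post-selection
harvests), i.e. `countSamples(ExperimentDesign())` = 222 sequencing
samples. `nLibraries` enters only this sample arithmetic: the two
libraries of the screen are separate constructs analysed in parallel, so
the simulator generates one library's replicate set at a time.

## The fitness model and score scale

Let $d$ be the wild-type growth cadence (default $d = 2$ doublings per
harvest interval). A variant $v$ with fitness $\beta_v$ grows by the
factor $2^{d + \beta_v}$ per interval. Scores are therefore on an
interpretable doubling-rate scale, anchored at wild type:

* $\beta = 0$: grows exactly like wild type;
* $\beta = -2$ (with $d = 2$): cells not growing at all
  ($2^{2-2} = 1\times$ per interval);
* $\beta = +1$: cells doubling three times per interval
  ($2^{2+1} = 8\times$).

Estimation proceeds per condition, independently:

1. **Filtering** (`filterVariants()`): a variant is kept iff its mean
   count over the replicate × timepoint grid is ≥ 4, its fraction of
   zero cells is ≤ 10/12, and its fraction of zero T0 cells is ≤ 2/3 —
   all inclusive. The fractions (not the integer counts) are the
   configurable quantities, so other designs reuse the same rules.
2. **Wild-type normalization** (`normalizeCounts()`): counts are
   log2-transformed (log2, not natural log, precisely so slopes stay on
   the doubling scale) and centered per sample on the synonymous
   (wild-type-encoding) pool; the median is the default center as it is
   robust to a few outlying synonymous variants (mean available via
   `center = "mean"`). Each trajectory is then anchored at its own first
   time point, making slopes translation-free.
3. **Regression** (`scoreTrajectories()`): the normalized trajectory is
   regressed on the time index $t = 1, \dots, T$ (not on real time), so
   the slope is the per-interval growth-rate difference from wild type.
   The per-replicate ordinary-least-squares slopes are averaged;
   the standard error is their standard deviation over $\sqrt{R}$
   (an infinite sentinel when $R = 1$). This replicate-based regression
   is deliberately the whole model: a full Bayesian enrichment scorer
   would add shrinkage but the quantities defined here — the score scale
   and the decision rules below — do not depend on it.

`scoreAll()` chains the three per condition into a `ScoreMatrix`
(variants × conditions, assays `beta`/`se`/`nReps`).
`dmsoRecenter()` then forms the drug-specific score
$\gamma_{v,\mathrm{inh}} = \beta_{v,\mathrm{inh}} - \beta_{v,\mathrm{DMSO}}$,
with standard errors combined in quadrature.

Because wild-type growth is pinned to $d$ doublings per interval in
every condition (growth-rate-controlled dosing), $\beta$ values are
directly comparable across inhibitors; no further affine recentering is
applied by default.

## Classification rules

A **resistance mutation** for an inhibitor satisfies both:

* a one-sided test of $\beta_{\mathrm{inh}} > 0.5$ — upper-tail normal
  probability of $(\beta - 0.5)/se$ — at the 0.1 cutoff, and
* $\beta_{\mathrm{DMSO}} \le 0$ (effect size only, no test), ensuring
  the advantage is inhibitor-specific rather than global.

The test is a frequentist reading of the decision boundary using the
replicate-derived normal approximation; an `seFree` mode (pure effect
size, $\beta > 0.5$) supports single-replicate designs. On $\gamma$,
**gain-of-function** is $\gamma > 0.75$ and **loss-of-function**
$\gamma < 0$; all classification inequalities are strict on the
call side and inclusive on the DMSO side, exactly as defined. A
consequence worth noting (and asserted in the tests): every resistance
mutation necessarily has $\gamma > 0.5$.

Aggregations: `resistancePositions()` (positions with ≥ 1 resistance
mutation), `hotspotCounts()` (position × inhibitor-type counts of
resistance events, plus the per-mutation expansion whose row sums equal
the position tiles), `sharedResistanceSets()` (the 7-region Venn
partition of distinct resistance mutations across type I, type II and
type I½ inhibitors), and `differentialSensitivity()` (variants GOF under
one inhibitor and LOF under another — by construction two disjoint
sets). Whether differential sensitivity should additionally demand the
resistance test in the GOF condition is genuinely open; the threshold
rule is the default and `requireTest = TRUE` exposes the stricter mode.
`pearsonMatrix()` compares conditions by pairwise-complete Pearson
correlation (raw or DMSO-subtracted via `useGamma`; pairwise rather than
listwise deletion so per-condition filter differences do not erase the
matrix, with `nPairs` reported so sparsity stays visible).

## What the simulator emulates — and what it does not

`drawGroundTruth()` + `simulateExperiment()` generate the study
conditions with known truth:

* **Library**: 20 substitutions per position (19 missense + 1
  synonymous) over 1059–1345, plus a stop-control variant every 11
  positions with inclusive stepping from the first position
  (287 × 20 + 27 = 5767 variants). The screen's own library additionally
  contained fill-in and re-synthesis variants, so its total (~5764) is
  not forced here; the enumeration rule, not the historical total, is
  the specification. The shipped wild-type sequence is a deterministic
  synthetic stand-in (the real protein sequence can be supplied to
  `buildLibrary()`), which affects only variant naming, never scores.
* **DMSO fitness**: a two-component mixture — wild-type-like
  $N(0, 0.15)$ with weight 0.55 and loss-of-function $N(-d, 0.4)$ —
  reproducing the bimodal DMSO distribution characteristic of kinase
  DMS. The weights and spreads are a realistic single choice, not fitted
  quantities.
* **Inhibitor fitness**: $\min(\beta_{\mathrm{DMSO}},\,-d)$ — everything
  is drug-sensitive — except planted `resistanceSpec` entries. Planted
  resistance effects in recovery experiments also plant a small negative
  DMSO effect for the same variants, because a resistance mutation is by
  definition inhibitor-specific; without that, the DMSO gate would
  reject half the plants by construction and a recovery experiment would
  measure the generator rather than the classifier. Nonsense variants
  sit at the dead level $-d$ everywhere.
* **Counts**: latent abundances start equal, propagate by
  $2^{d+\beta}$ per interval, and are sampled multinomially per
  (condition, replicate, timepoint) sample at the configured depth
  (Poisson available). T0 is drawn once per replicate and shared across
  conditions, as in the screen. Seed streams are derived per
  (replicate, condition) by stable integer mixing, so runs are
  reproducible and replicates independent.
* **Noiseless mode** emits exact expected read shares as real-valued
  counts (unrounded — rounding would break exact recovery); noiseless
  counts are strictly positive, so the pseudocount (default 0.5, a
  continuity correction for zero cells that survive filtering) can and
  should be 0 there, making the pipeline recover planted fitness to
  floating-point accuracy. Exact depth-invariance likewise holds at
  pseudocount 0.

The simulator does **not** model IL-3 withdrawal kinetics, dose–response
pharmacology, PCR jackpotting or index hopping, position-correlated
fitness structure, or epistasis; passing recovery tests therefore show
correctness of the estimator under the stated sampling model, not
robustness to every artifact of real sequencing data.

## Worked example

```{r example}
lib <- buildLibrary(1059, 1345)
design <- ExperimentDesign(conditions = c("crizotinib", "DMSO"))
plant <- rbind(
  data.frame(position = 1228, mutAa = "N", condition = "crizotinib",
             beta = 1.5),
  data.frame(position = 1228, mutAa = "N", condition = "DMSO",
             beta = -0.3))
cfg <- SimConfig(depthPerSample = 1e6, seed = 42, resistanceSpec = plant)
truth <- drawGroundTruth(lib, design, cfg)
sim <- simulateExperiment(truth, design, cfg)

sm <- scoreAll(sim)
labels <- classifyAll(sm)
subset(as.data.frame(labels), position == 1228 & mutAa == "N")
```

The planted resistance mutation is recovered near its true
$\beta = 1.5$, passes the one-sided test and the DMSO gate, and is
labeled GOF on the $\gamma$ scale.

## The machine-learning protocol

The prediction task — experimental fitness of (variant, inhibitor) pairs
from interpretable features — is prone to overfitting at this data size,
and the protocol exists to keep evaluation honest:

* **Exclusions**: DMSO and the single type I½ inhibitor are excluded;
  with only one dataset of each, a model would learn them by memorizing
  the condition.
* **Features**: the evolutionary-likelihood feature (protein
  language-model log-likelihood-ratio role) is in every model and
  constrained to act positively; the stability-difference feature is
  constrained negatively (its printed identity is typographically
  ambiguous in the source material, so the constraint map is
  reassignable); the 12 other features are coarsened into 4–5 bins
  represented by the bin median (`makeBinSpec()` / `binFeatures()`),
  a variance-reduction device that also keeps them interpretable.
* **Split** (`makeSplit()`): held out for testing are all rows of one
  type I and one type II inhibitor, a floor-rounded 20% of positions,
  and 2 amino-acid identities — so with 287 positions and 20 amino
  acids, training covers 230 positions and 18 amino acids, and every
  test row differs from all training rows in at least one whole block.
* **Cross-validation** (`makeCvFolds()`): the 230 training positions
  are partitioned into 10 disjoint parts of 23; each fold also draws a
  block of 2 amino acids (without replacement within a fold,
  independently across folds — re-use across folds is unavoidable since
  10 × 2 > 18, which is how "re-sampling" is realized here).
  Fold $i$ validates on rows hitting part $i$'s positions *or* amino
  acids.
* **Model search** (`tuneTrainSelect()`): feature subsets are enumerated
  exhaustively around the fixed feature (`enumerateFeatureSets()`;
  $2^{13} = 8192$ for the full panel — at desk scale a sampled subset of
  sets plus the full set is the sensible sweep). Hyperparameters
  (booster type, depth, trees, learning rate, split loss, column
  subsample, L1/L2, growth policy) are tuned per feature set on an
  internal 80/20 split by random search within a trial budget,
  minimizing MSE — a deliberately dependency-free stand-in for Bayesian
  optimization that honors the same search contract. Sets are ranked by
  mean CV Pearson r; the winner is refit on all training rows and
  evaluated per inhibitor on the held-out blocks.

The regressor is a pluggable contract (`xgboostRegressor()` is the
shipped backend); a backend lacking monotone-constraint support fails
loudly rather than silently dropping the constraints.
`simulateFeatureTable()` provides synthetic feature tables (all features
are labeled stand-ins; no structures, docking or language models are
computed) so the protocol is exercisable end to end.

## Numerical choices and problem sizes

* Filter thresholds are inclusive; missing grid cells count as zeros.
* Degenerate scoring inputs: fewer than 2 time points is an error; a
  condition without synonymous variants cannot be normalized and errors.
* Zero-variance columns make Pearson r undefined; correlation cells with
  fewer than 3 shared variants are NA with a warning.
* Classification at exact boundaries: $\beta_{\mathrm{inh}} = 0.5$ gives
  $p = 0.5$ (never resistant); $\gamma = 0.75$ and $\gamma = 0$ are
  neutral.
* The test suite and examples run the full 287-position library for
  noiseless recovery and a 3-condition, depth-$10^6$ multinomial screen
  for stochastic recovery (Pearson to truth ≥ 0.95, planted-resistance
  sensitivity ≥ 95%, null false-positive rate within the nominal test
  level); these sizes keep a complete run in the low minutes on one CPU
  while exercising every stage at realistic depth.

## Limitations

* The scorer is a per-replicate OLS mean/SE model; it does not produce
  posteriors or shrink extreme low-count variants, so very sparse
  variants rely on the count filters for protection.
* The normal approximation of the resistance test uses an SE from 3
  replicates (2 degrees of freedom); its nominal level is approximate,
  which the null-simulation test monitors empirically.
* Real-data headline quantities (specific condition-pair correlations,
  counts of differential or shared mutations, ML test correlations)
  depend on the deposited sequencing data and externally computed
  features, and are out of scope here; the package reproduces the
  worked-example arithmetic, the design arithmetic, and the recovery
  behavior of the method itself.
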