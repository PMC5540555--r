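---
title: "Modeling sgRNA on-target activity from 30-mer context"
author: "guidepred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sgRNA on-target activity from 30-mer context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidepred)
```

## The problem

SpCas9 guides targeting the same gene differ widely in how efficiently
they induce cleavage, and much of that variation is encoded in the local
sequence. `guidepred` models on-target activity from the 30-nucleotide
context of a target site — 4 nt upstream, the 20-nt protospacer, the NGG
PAM (so positions 26–27 carry "GG"), and 3 nt downstream — plus two
assay covariates (percent peptide and amino-acid cut position) where
available. The model predicts a continuous activity score per guide;
binary "active" calls for threshold metrics mark the per-gene top 20% of
scores, matching how knockout assays are typically summarized.

## The feature encoding

Each guide becomes a deterministic vector of 9632 named features:

* **Position-specific indicators (PSF).** For k = 1..4, one binary
  column per (k-mer, start position) pair — `G_24` is "G at position
  24", `GAGG_24` is "GAGG starting at 24". Block sizes are
  (31−k)·4^k: 120, 464, 1792 and 6912 columns. Exactly 31−k entries of
  each block are 1 for any sequence, which the tests assert as a
  conservation invariant.
* **Position-independent counts (PIF).** For k = 1..4, the overlapping
  occurrence count of each k-mer anywhere in the 30-mer: 4 + 16 + 64 +
  256 = 340 columns, each block summing to 31−k.
* **Thermodynamics.** The 30-mer is transcribed (T→U) and folded with
  the ViennaRNA tools at their defaults: `RNAfold` yields the minimum
  free energy (kcal/mol, ≤ 0; exactly 0 for sequences that cannot
  base-pair, like poly-A) and `RNAheat` the specific heat
  (kcal/(mol·K)). `RNAheat` produces a temperature sweep; the package
  reads it out at a single configurable temperature (default 37 °C,
  evaluated on a 3-point window because the tool requires a range).
  When the tools are absent these features can be disabled in the
  `feature_spec()`; they are never silently zero-filled.
* **Auxiliary covariates.** Amino-acid cut position and percent
  peptide, taken from the guide table; missing values are imputed with
  the training-set median and the imputation values travel inside the
  trained model so prediction-only FASTA input is handled consistently.

Column order is fixed (PSF blocks by k, position ascending, k-mer
lexicographic within a position; then PIF blocks; then `mfe`,
`specific_heat`, `amino_acid_cut_position`, `percent_peptide`), so
matrices, importance tables and models are interchangeable across runs.
120 + 464 + 1792 + 6912 + 340 + 2 + 2 = 9632.

The featurizer does not enforce the PAM: positions 26–27 are encoded as
given, and the validator only warns (optionally) when they are not
"GG", because exploratory non-PAM inputs are legitimate.

## Feature selection

With ~10^4 features and a few thousand guides, the downstream linear
model needs a much smaller, informative feature set. Selection is a
two-stage filter:

1. **Repeated random-forest importance.** A classification forest of
   the binary labels is fitted `repeats` times (default 30, seeds
   `seed`, `seed+1`, …) with up to 500 trees, and each feature's Mean
   Decrease Gini importance is averaged. Averaging matters: a single
   forest's Gini values are noticeably seed-dependent at this
   dimensionality, and the tests assert that the averaged estimate has
   lower variance. Features with mean importance strictly above a raw
   (unnormalized) threshold are kept, in importance order; 0.18 is the
   default operating point. Thresholding is deliberately applied to raw
   Gini values — the normalized view is only used for the category
   summary figure — and selection is strict-greater, which makes nested
   thresholds give nested feature sets. The forests are classification
   forests even though the scorer is a regression, because Mean
   Decrease Gini is a classification impurity measure. The
   implementation uses `ranger` (impurity importance, single-threaded
   for determinism), whose Gini scale matches the classic
   `randomForest` measure.
2. **Single-pass ANOVA redundancy filter.** One linear model of the
   continuous score on all selected features jointly; features whose
   marginal coefficient p-value exceeds `anova_alpha` (default 0.05)
   are dropped in a single pass, with no refitting loop. Marginal
   t-tests were chosen over sequential (Type I) ANOVA so that retention
   does not depend on column order. Exactly collinear (aliased)
   features are dropped and reported rather than raising an error.

A guard caps the selected set at `n_rows − 2` (keeping the most
important features) before SVM training, since a linear fit with more
features than observations is ill-posed. Raw Gini magnitudes scale with
the number of observations and the class balance, so the 0.18 default
is an operating point for datasets of a few thousand guides; on other
data (including the null simulations below, where there is nothing real
to select) the threshold should be adjusted to the importance scale
actually observed.

## The scorer

An epsilon-regression SVM with a linear kernel (cost 1, epsilon 0.1,
features standardized; zero-variance features pass through unscaled
with a warning) is fitted on the continuous activity scores.
Regression-then-rank was chosen over classification because the
evaluation uses both a regression metric (RMSE) and threshold-swept
curves of the continuous predictions; a probability-output
classification mode is available behind `svm_config(mode =
"classification")` for completeness. Prediction aligns columns by
feature name, so column order and extra columns are irrelevant, and a
missing feature is a schema error rather than a silent zero.

## Evaluation

Cross-validation is leave-one-gene-out: all guides of one gene form the
test fold, so no gene informs its own predictions — gene-level leakage
is the dominant optimism risk for guide models. By default feature
selection is re-run inside every training fold; a faster global
selection mode exists but is labeled optimistic, because the held-out
gene's labels then help choose its own features. Held-out predictions
are pooled across folds into single curves (rather than averaging
per-fold curves), matching standard practice.

Metrics, all computed over every unique prediction threshold with tied
predictions treated as one threshold:

* **ROC / AUROC** by the rank (Mann-Whitney) formula with half credit
  for ties; the tests assert it equals the trapezoidal area under the
  curve to 1e−10, and agreement with an independent implementation.
* **PR / AUPR** with step-wise area (precision × recall increment);
  linear interpolation in PR space is biased and is not used. A
  constant predictor scores the positive prevalence under this rule.
* **Sensitivity–specificity curve**, the ROC in (specificity,
  sensitivity) coordinates.
* **MCC threshold curve** and its maximum, with MCC defined as 0
  whenever a confusion-matrix marginal is 0.
* **RMSE** of predicted versus observed continuous scores.

## The simulator

`simulate_guides()` generates the ground-truth datasets every stage is
tested against: i.i.d. uniform nucleotides with "GG" fixed at positions
26–27, genes assigned round-robin (default 17, the size of the public
benchmark this package is shaped around), scores from a sparse linear
function of planted sequence features plus Gaussian noise, labels as
the per-gene top 20%, and null auxiliary covariates (percent peptide ~
U(0,100), cut position ~ U(1,500), no planted effect).

The default planted truth reflects the composition effects reported for
active guides — G-rich and A-rich, T-depleted — as counts (`G` +0.5,
`A` +0.5, `T` −0.5) plus two positional motifs inside the protospacer
(`G_20` +2, `T_18` −2). The magnitudes are documented design choices,
not empirical claims. Two considerations fixed them: the three count
coefficients are equal so that no planted count is dominated by the
dimer-count surrogates of a stronger one, and the motifs are
single-nucleotide indicators because impurity importance divides credit
among correlated features — a planted effect on a rare k-mer (present
in 1/16 of guides or less) is recovered only through its correlated
surrogates, never by name, which would make "find the planted feature
by rank" an unfair test of a working method. The default noise sd of 1
is roughly half the planted signal's sd (~2), a moderate-noise regime;
recovery tests also use sd 0.25 (low noise) and sd 0 (noiseless).

What the simulator does *not* emulate: assay-specific noise (flow
cytometry gating, resistance-assay dropout), gene-specific composition
biases, shared off-target structure, or correlated covariates. Passing
the synthetic-recovery tests therefore shows the pipeline recovers
planted linear sequence effects under uniform sequence backgrounds — it
does not by itself certify performance on real screens.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale versions of each
experiment, chosen as the package's own defaults for a laptop-class
single-core run: recovery and cross-validation simulations use 2000
guides over 5 genes with forests of 150 trees and 2–3 importance
repeats; structural cross-validation checks use 17 genes at 20–30
guides per gene with a reduced (k ≤ 2, sequence-only) encoding, since
fold bookkeeping does not depend on the encoding's width. Full-scale
settings (500 trees, 30 repeats, the complete 9632-column encoding) are
the exported defaults and are what `reproduce_reference_study()` runs
on a real guide table; at benchmark scale (~5000 guides, 17 genes) that
is a multi-hour computation.

Other numerical conventions: ties in score-rank labeling break by input
row order (stable, so labeling is idempotent); per-group positive
counts round half up; importance ties keep column order; the MCC
zero-marginal convention is 0; curve sweeps include the all-negative
binarization so ROC curves always start at (0,0).

## Limitations

* The importance threshold is an absolute Gini value; it does not
  transfer across dataset sizes or class balances without adjustment.
* Gini importance spreads across correlated features, so importance
  rank understates rare motifs that act through correlated proxies.
* The ANOVA filter tests linear marginal effects only; features useful
  purely through interactions can be dropped.
* Thermodynamic features depend on the installed ViennaRNA version;
  the feature-matrix manifest records the configuration so runs can be
  compared like-for-like.
* No off-target modeling: the package scores on-target activity only.
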