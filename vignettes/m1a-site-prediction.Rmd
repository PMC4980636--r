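---
title: "Predicting N1-methyladenosine sites from sequence windows: model, encoding and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting N1-methyladenosine sites from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m1Apred)
```

## The problem

N1-methyladenosine (m1A) is a reversible RNA modification: a methyl group on
the N1 position of adenosine that also leaves the base positively charged.
Transcriptome-wide immunoprecipitation experiments (MeRIP-seq and related
protocols) locate m1A-containing *regions*, but they cannot pinpoint which
adenosine inside a peak is actually modified. This package addresses the
complementary computational problem: given a fixed-length RNA window centered
on a candidate adenosine, predict whether that adenosine is methylated.

The unit of analysis is a **window**: an odd-length sequence (41 nt by
default) over {A, C, G, U} whose center base is A. Windows labeled positive
have an experimentally supported modified center; negatives have a center
adenosine with no such support. DNA-alphabet input is transliterated (T to U)
because windows are usually extracted from genome coordinates; ambiguity
codes are rejected because the encoder defines no coordinates for them.

## Sequence representation

Each position contributes four features.

**Chemical-property triple (x, y, z).** The four bases divide three ways by
chemistry: purines (A, G) have two rings, pyrimidines (C, U) one; G and C
pair through strong hydrogen bonding, A and U through weak; A and C carry an
amino group, G and U a keto group. Encoding each dichotomy as one bit gives

| base | x (ring) | y (H-bond) | z (functionality) |
|------|----------|------------|--------------------|
| A    | 1        | 1          | 1                  |
| C    | 0        | 0          | 1                  |
| G    | 1        | 0          | 0                  |
| U    | 0        | 1          | 0                  |

The four triples are pairwise distinct, so the NCP channels alone already
identify the base at each position.

**Cumulative nucleotide density d.** The density at position $i$ is the
frequency of the base occupying position $i$ within the prefix ending there:

$$d_i = \frac{1}{i}\,\bigl|\{\,k \le i : n_k = n_i\,\}\bigr|$$

so $d_1 = 1$ always, and a homopolymer is 1 everywhere. Density injects
sequence-order and composition information that the memoryless NCP channels
lack. We read the prefix-normalizing denominator as the position index $i$,
giving exactly one density value per position; this is the only reading
consistent with the encoding's stated dimensionality of $4 \times l$ (164
for $l = 41$): three chemistry bits plus one density per position.

Feature vectors are laid out **position-major** — for each position the
enabled channels in the fixed order (x, y, z, d). No ordering is canonical
for an RBF-SVM (any fixed permutation of features yields the same kernel);
the choice is frozen and recorded in file headers for reproducibility.
Features need no further scaling: every channel already lies in [0, 1].

A pseudo dinucleotide composition (PseDNC) encoder is included as the
comparison baseline: 16 dinucleotide frequencies plus `lambda` tiered
correlation terms weighted by `w`, each tier the mean squared difference of
standardized physicochemical properties between dinucleotides that distance
apart, all normalized by $1 + w\sum\theta$ so the vector sums to 1. The
property values (enthalpy, entropy, free energy per dinucleotide) are
**loaded from a user-editable TSV**, not hard-coded: the canonical values
live in the thermodynamics literature and transcribing them into code risks
silent error. The shipped example table uses published RNA nearest-neighbor
values; since properties are standardized across the 16 dinucleotides at
load, results are invariant to their units.

## Classifier

An RBF-kernel support vector machine (via e1071/libsvm). The cost $C$ and
kernel width $\gamma$ are selected by grid search maximizing stratified
inner cross-validated accuracy (5 folds by default), with ties broken toward
the smallest $C$, then the smallest $\gamma$ — a deterministic rule that
makes the winner independent of grid enumeration order. Default grids follow
the libsvm practitioner convention, $C \in \{2^{-5}, 2^{-3}, \ldots,
2^{15}\}$ and $\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$; both are
ordinary configuration and can be narrowed for quick runs or widened for
final models. Accuracy is the default selection criterion to match the
accuracy-centric reporting tradition of this literature; AUROC selection is
available by flag. Predictions are SVM decision values oriented so larger
means more likely modified; the call threshold is 0, and decision values
(not calls) feed ROC/PR analysis.

## Benchmark construction

Positives from peak-derived windows are typically redundant. Windows sharing
**more than** 80% identity are removed by greedy incremental clustering in
input order: a window is kept iff its identity to every previously kept
window is at most the threshold, with identity exactly at the threshold
retained. Because all windows are equal-length and anchored on the center
adenosine, identity is position-wise (Hamming-based) matching — for such
windows the ungapped measure is the natural one, it is exactly testable, and
it avoids an external clustering binary. Redundancy reduction applies to
positives by default (negatives pools are usually dominated by sheer volume,
not redundancy) and can be extended to negatives by flag. The 80% threshold
is looser than the 40% sometimes preferred for homology control; tighter
screening is only advisable when enough data survives it.

The negative pool vastly outnumbers positives, and imbalanced training
distorts accuracy-based evaluation, so balanced datasets are built by
sampling negatives without replacement to match the positive count. The draw
is repeated (ten times by default) with derived seeds `seed + i`, and models
are compared across repeats to show insensitivity to the particular
negatives drawn. Identical sequences appearing in both classes are rejected
as contamination rather than silently kept.

## Validation protocols

* **Jackknife (leave-one-out)**: each window is scored by a model trained on
  the remaining $n-1$; the least arbitrary resampling estimate, used for
  headline numbers.
* **Stratified k-fold** (k = 10 by default): the cheaper protocol for
  repeated experiments (negative-resampling robustness, ablations,
  classifier comparisons).
* **Independent cross-dataset tests**: train on one species or cell line,
  score another; running all ordered pairs yields the transfer matrix.

Reported metrics are sensitivity, specificity, accuracy (as percentages) and
the Matthews correlation coefficient, all recomputable from the reported
confusion counts; plus ROC and precision-recall curves with their areas.
AUROC is trapezoidal over tie-grouped thresholds, which equals the
Mann-Whitney U statistic normalized by $n_{pos} n_{neg}$ (an identity the
tests verify to 1e-9). AUPRC uses the step-wise precision-at-recall-change
convention, because trapezoidal interpolation is optimistic for PR curves;
the convention is recorded in report metadata. An MCC whose denominator
vanishes (an empty confusion-table marginal) is reported as `NaN` with a
warning, never clamped to 0 — an undefined value should stay visible.

**Hyperparameters under resampling.** A fully nested grid search inside
every jackknife fold costs $n \times |grid|$ trainings. By default $C$ and
$\gamma$ are selected once on the full dataset and held fixed across folds;
this mild optimism is shared by common practice, and a `nested = TRUE`
option provides the leakage-free variant when compute allows. The same
select-once policy applies to k-fold runs. Cross-dataset models select
hyperparameters on the training dataset only, and their decision threshold
stays at 0 rather than being tuned per test set.

## Synthetic benchmark generator

Real m1A benchmarks derive from MeRIP-seq peaks; this package instead ships
a generator of adenosine-centered windows with *known* signal, so every
claim is testable end to end without downloads. Negatives draw each
non-center position i.i.d. from a background distribution (uniform by
default). Positives mix background with a positional signal at chosen
offsets: with `signal_strength` $s$, a signal position follows
$(1-s)\,\text{background} + s\,\text{signal}$. Defaults — 500 windows per
class, six fully committed signal positions flanking the center, $s = 1$ —
give a nearly separable problem (a negative matches all six signal bases
with probability $4^{-6}$), which is the regime where a sound
implementation must score almost perfectly; $s = 0$ makes the classes
exchangeable, pinning chance-level behavior. A two-domain variant shares or
disjoins the signal positions between two independently seeded datasets,
emulating cross-cell-line transfer (shared determinants) versus
cross-species failure (no shared determinants).

What the generator does *not* emulate: real positional dependence and motif
structure around m1A sites (e.g. GC-rich context), transcript-level
composition bias, redundancy between windows, and label noise from
peak-to-site ambiguity. Passing the synthetic benchmarks therefore
demonstrates that the encoder preserves positional composition signal and
the pipeline is correct and leak-free — not that any particular accuracy
will be achieved on biological data.

## Numerical and design notes

* All randomness (sampling, fold assignment, generation) flows through
  per-call seeds; library code saves and restores the caller's RNG state.
* Stratified folds deal each class round-robin after a seeded shuffle; fold
  assignments are recorded in reports for audit.
* Validation problem sizes used by the shipped test suite: 500 + 500
  windows with 10-fold CV for signal recovery and cross-domain transfer;
  150 + 150 for the ablation study (with the 5 × 5 grid around the
  conventional region); smaller short-window datasets for the
  protocol-equivalence and determinism checks. These sizes give stable
  statistics at interactive runtimes.
* Degenerate inputs fail loudly: empty sequences, single-class datasets,
  classes smaller than k, one-class score vectors, mixed window lengths.
* Positions are 1-based everywhere a message or output names one; the
  center of a length-$l$ window is $(l+1)/2$.

## Known limitations

* Ungapped identity is blind to similarity between shifted windows; it is
  intended for center-anchored windows only.
* The select-once hyperparameter policy is slightly optimistic relative to
  nested selection (available but slow).
* The PseDNC example property table is illustrative; for published
  comparisons, supply the property values of record.
* No upstream peak processing: the package begins at pre-extracted windows
  and makes no attempt to map transcriptome coordinates.
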