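---
title: "Position-specific nucleotide-pair features for m6A site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific nucleotide-pair features for m6A site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppsvm)
```

## The problem

N6-methyladenosine (m6A) is the most common internal mRNA modification.
Experimental maps of m6A sites exist for several species, but deciding
whether a given adenosine in a given sequence context is methylated is a
supervised classification problem: given a fixed-length RNA window centered
on a candidate A (51 nt in the common benchmark sets — the site plus 25 nt
of flank on each side), predict methylated versus unmethylated. The
discriminative signal is positional: m6A sites sit in a degenerate DRACH
consensus (D = A/G/U, R = A/G, H = A/C/U) and carry weaker class-specific
composition biases across the flanks.

`nppsvm` implements a feature encoding that targets exactly this structure
— nucleotide pair position specificity (NPPS) — together with an RBF-kernel
SVM and the standard evaluation protocol for this field.

## The NPPS encoding

Let the training set consist of positive windows $S^+$ (m6A) and negative
windows $S^-$ (non-m6A), all of length $l$. For a gap parameter $\xi \ge 0$
(the number of nucleotides *between* the two members of a pair, so
$\xi = 0$ is the contiguous dinucleotide) and each class, two positional
frequency matrices are tallied:

* $T_s$, $4 \times l$: $f_{i,k}$ is the probability of nucleotide $i$
  (rows A, C, G, U) at position $k$;
* $T_d$, $16 \times (l - \xi - 1)$: $F_{j,k}$ is the probability of the
  ordered pair $(s_k, s_{k+\xi+1})$ being pair $j$ (rows AA, AC, ..., UU in
  lexicographic order), indexed by the position $k$ of its first member.

A query window $s$ is scored position by position with the conditional
probability of the first pair member given the second. If the pair at
position $k$ has row index $j$ in $T_d$ and its second member has row index
$i$ in $T_s$, then under the positive class

$$p_k^+ \;=\; \frac{F^+_{j,k}}{f^+_{i,\,k+\xi+1}},$$

$p_k^-$ is the same quantity under the negative profiles, and the feature
is the difference $p_k = p_k^+ - p_k^-$. A single interval $\xi$ yields
$l - \xi - 1$ features; the joined encoding concatenates the blocks for
$\xi = 0, 1, \dots, 6$ (ascending $\xi$, ascending position within a
block), which for $l = 51$ gives $50 + 49 + \dots + 44 = 329$ dimensions.
Because each conditional lies in $[0, 1]$, every feature lies in
$[-1, 1]$, and no feature scaling is applied before the SVM.

The encoding captures two kinds of information at once: *local*
correlation between nucleotides at controlled separations (through $\xi$),
and *global* between-class positional differences (because the profiles
are tallied on whole classes and differenced).

### Numerical conventions

* **Gap semantics.** The pair at position $k$ spans positions
  $(k, k+\xi+1)$: $\xi$ counts intervening nucleotides. This is the only
  convention under which a 51-nt window yields $50 - \xi$ pair positions
  ($50, 49, \dots, 44$ for $\xi = 0 \dots 6$), with $\xi = 0$ the
  contiguous dinucleotide.
* **Conditioning direction.** The conditional is on the *second*
  (downstream) member of the pair; the denominator is the single-nucleotide
  frequency at position $k + \xi + 1$.
* **Zero denominators.** If a class never shows the conditioning
  nucleotide at that position ($f_{i,k+\xi+1} = 0$, which forces
  $F_{j,k} = 0$ too), the conditional for that class is defined as 0 — the
  limit of $F/f$ under additive smoothing as the pseudocount goes to 0.
  This keeps all features bounded.
* **Pseudocount.** Additive smoothing $\alpha$ is available on
  `fit_class_profile()` / `fit_npps_profiles()` (counts become
  $(c + \alpha)/(n + 4\alpha)$ for single nucleotides and
  $(c + \alpha)/(n + 16\alpha)$ for pairs). The default is $\alpha = 0$,
  matching the plain frequency definition of the matrices; the
  zero-denominator rule covers the resulting degeneracies. With any
  $\alpha \ge 0$ the conditionals remain in $[0, 1]$.
* **Indexing.** Internally everything is 1-based (native R); all
  user-facing positions are likewise 1-based, so "position 26" of a 51-nt
  window is the candidate A.

## Classifier

An RBF-kernel SVM (through `e1071`, the R binding of LibSVM) classifies
the encoded windows; labels are +1 (m6A) / −1 (non-m6A) and the decision
threshold is 0, with a score of exactly 0 mapped to +1. The two
hyperparameters — penalty $C$ and kernel width $\gamma$ — are chosen by
grid search maximizing the F-score (F1 of the positive class, defined as 0
when precision + recall is 0) under stratified inner cross-validation
(5 folds by default). The default grids follow the exponential LibSVM
convention, $C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ and $\gamma \in
\{2^{-15}, 2^{-13}, \dots, 2^{3}\}$, with a finer $\times 2$-stepped
$\gamma$ option; published optima for benchmark m6A sets (for example
$C = 2048, \gamma = 2^{-13}$ and $C = 32, \gamma = 0.125$) lie inside
these ranges. Ties are broken toward smaller $C$, then smaller $\gamma$,
so the search is deterministic given the seed.

## Evaluation protocol

Performance is reported as sensitivity, specificity, accuracy and
Matthews correlation,
$$\mathrm{Sn} = \frac{TP}{TP+FN}, \quad
  \mathrm{Sp} = \frac{TN}{TN+FP}, \quad
  \mathrm{Acc} = \frac{TP+TN}{TP+TN+FP+FN},$$
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
with MCC defined as 0 when a denominator factor vanishes and Sn/Sp
reported as `NA` (not 0) when their class is absent. On a balanced
evaluation set, $\mathrm{Acc} = (\mathrm{Sn} + \mathrm{Sp})/2$ exactly.
Threshold-free ranking is summarized by AUROC (Mann–Whitney pair counting,
ties at 1/2) and AUPRC (step-wise precision–recall integral), computed
from the decision scores directly — no probability calibration is applied.

`kfold_cv()` uses stratified folds with a seeded shuffle. Two design
points deserve emphasis:

* **Per-fold encoder refitting.** The NPPS profiles are themselves
  estimated from labeled data, so fitting them on the full dataset before
  cross-validation would leak validation labels into the features.
  `kfold_cv()` refits the profiles inside every training fold and encodes
  the held-out fold with those training-fold profiles. The same argument
  applies one level down: during the nested grid search the encoder is
  refitted inside every *inner* fold as well. This matters in practice —
  encoding inner-validation samples with profiles that had seen them
  inflates the inner F-score (we observed ≈ 0.98 inflated versus ≈ 0.96
  honest on the synthetic defaults) and biases the search toward
  under-regularized, large-$C$ configurations that generalize measurably
  worse. Whole-dataset fitting before CV may be closer to some published
  pipelines, which do not state their choice; it can be emulated by
  encoding once with `fit_npps_profiles()` on everything and evaluating
  with `grid_search()`/`svm_train()` by hand, but it is deliberately not a
  mode of `kfold_cv()`.
* **Pooled and averaged reporting.** The primary report aggregates the
  confusion counts of all folds (pooled); per-fold reports and their mean
  accuracy are also returned, since published k-fold numbers are sometimes
  fold averages.

`jackknife()` is leave-one-out: `kfold_cv()` with $k = n$, in which case
the partition degenerates to singletons and no randomness remains.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` produce labeled fixed-length
windows so the whole pipeline is testable without external downloads.
Positive windows draw the five positions under a DRACH-like
position-weight block (D, R, A, C, H columns, uniform over their allowed
bases) mixed with the background by `motif_strength`; all other positions,
and negative windows everywhere, are i.i.d. background (uniform by
default). The central base is forced to A in both classes by default,
mirroring real benchmark sets where negatives are also adenosine-centered.

Defaults are 300 windows per class, 51-nt windows, and
`motif_strength = 1`: at genuine m6A sites the DRACH consensus is
effectively obligate, so the realistic default makes the (still
degenerate) consensus fully penetrant in positives. Under these defaults
the Bayes-optimal accuracy is analytically $\approx 0.965$: a negative
window matches the degenerate consensus with probability
$\tfrac{3}{4} \cdot \tfrac12 \cdot \tfrac14 \cdot \tfrac34 = 9/128
\approx 0.070$, such windows are indistinguishable from positives, and
half of them are necessarily misclassified on balanced data. Observed
10-fold pooled accuracies of 0.96–0.97 therefore indicate the encoder +
SVM operate near the information limit of this generator. With
`motif_strength = 0` the classes are exchangeable and pooled accuracy must
sit near 0.5 — a useful leakage detector, since any fold leakage shows up
as above-chance "accuracy" on null data.

What the generator does *not* emulate: transcriptome context, sequence
similarity structure between windows, conservation, secondary structure,
or motif-bearing unmethylated negatives (a harder negative regime can be
approximated by passing a custom `motif` for negatives via a second
generated set). Passing tests on synthetic data therefore demonstrates
correctness of the machinery and sane statistical behavior, not the
accuracy to expect on real benchmark datasets, where published accuracies
are far below the synthetic ceiling (roughly 0.77–0.90 depending on
species).

## Problem sizes and runtime choices

The shipped tests and the acceptance script use problem sizes chosen to
exercise every code path at desk scale: oracle comparisons on ≥ 50 random
instances with $l \le 10$, $n \le 8$, $\xi \le 3$; cross-validation checks
at 300 windows per class, 10 folds, intervals 0–6, with a reduced
$3 \times 3$ hyperparameter grid ($C \in \{1, 32, 1024\}$,
$\gamma \in \{2^{-7}, 2^{-4}, 2^{-1}\}$) spanning the default exponential
ranges; the full default grid is intended for real analyses.

## Degenerate inputs and edge behavior

* Empty FASTA files parse to empty datasets; empty feature matrices
  encode to $0 \times D$ with intact layout metadata.
* Ambiguous bases (N, R, Y, ...) are hard errors naming the record and
  position, with an opt-in skip-with-warning mode; DNA-style input (T,
  lowercase) is silently normalized to uppercase RNA, since public m6A
  datasets circulate in both alphabets.
* A window-center A check is available but off by default — it is a
  property of how benchmark windows were extracted, not of the encoding.
* Saved models embed an MD5 fingerprint of the encoder they were trained
  with; the prediction pipeline refuses a mismatched model/profile pair.
* Grid search requires both classes and at least `2 * inner_folds`
  samples; `kfold_cv()` requires at least $k$ members per class except in
  the $k = n$ (jackknife) boundary case, where stratification is
  impossible and the partition is plain leave-one-out.

## Known limitations

* Real-data accuracies from the literature are not reproducible here:
  the benchmark datasets are distributed through a webserver, and
  published pipelines do not state their fold randomization or whether
  profiles were fitted inside or outside CV. This package takes the
  statistically conservative choice (inside).
* The jackknife with a multi-point grid re-runs the grid search $n$
  times; for large $n$ this is expensive by construction. Use a
  pre-chosen $(C, \gamma)$ (single-point grids) or k-fold CV instead.
* No feature reduction, physicochemical encodings, probability
  calibration, or genome-scanning mode; inputs are pre-windowed
  sequences.
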