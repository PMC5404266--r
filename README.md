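# nppsvm

Prediction of N6-methyladenosine (m6A) sites in fixed-length RNA sequence
windows, for anyone studying mRNA modification from sequence: the package
encodes 51-nt adenosine-centered windows with **nucleotide pair position
specificity (NPPS)** features and classifies them with an RBF-kernel SVM.

## Method

For each class (m6A / non-m6A) and each gap `ξ` (number of nucleotides
between the two members of a pair; `ξ = 0` is the contiguous dinucleotide),
the encoder tallies two positional frequency matrices from training
windows of length `l`:

* `T_s` (4 × l): single-nucleotide probabilities `f[i, k]`, rows A,C,G,U;
* `T_d` (16 × (l − ξ − 1)): probabilities `F[j, k]` of the ordered pair
  `(s_k, s_{k+ξ+1})`, rows AA … UU.

A query window is scored at each position `k` by the conditional
probability of the first pair member given the second,
`p_k = F[j,k] / f[i, k+ξ+1]`, under the positive and the negative
profiles; the feature is the difference `p_k⁺ − p_k⁻ ∈ [−1, 1]`. Joining
the blocks for `ξ = 0…6` gives `Σ (l − ξ − 1) = 329` features for 51-nt
windows. An RBF-kernel SVM (LibSVM via `e1071`), with `C` and `γ` chosen
by F-score-driven grid search under stratified inner cross-validation,
separates the classes. Evaluation reports Sn, Sp, Acc, MCC (plus
F-score, AUROC, AUPRC) under stratified k-fold cross-validation or the
jackknife, refitting the encoder inside every training fold (and every
inner grid-search fold) so no validation information leaks into the
features. See the vignette in `vignettes/npps-methods.Rmd` for the full
model description and design rationale.

## Worked example

```r
library(nppsvm)

# synthetic 51-nt windows: positives carry a centered DRACH-like consensus
spec <- synthetic_spec(n_pos = 100, n_neg = 100, seed = 42)
ds <- generate_dataset(spec)
ds
#> npps_dataset: 200 windows of 51 nt (100 positive, 100 negative, 0 unknown)

profiles <- fit_npps_profiles(ds, intervals = 0:6)
profiles
#> npps_profile_set: window_length=51, intervals={0,1,2,3,4,5,6}, joined dimension=329, alpha=0
#>   fitted on 100 positive / 100 negative sequences

cv <- kfold_cv(ds, k = 5, intervals = 0:6,
               config = svm_config(C_grid = c(1, 32),
                                   gamma_grid = c(2^-7, 2^-4),
                                   inner_folds = 3),
               seed = 42)
cv
#> 5-fold cross-validation (pooled):
#> Sn = 99.00%  Sp = 93.00%  Acc = 96.00%  MCC = 0.9217
#> AUROC = 0.9832  AUPRC = 0.9767
#> per-fold mean Acc = 96.00%
```

Sn is the fraction of m6A windows recovered, Sp the fraction of non-m6A
windows rejected, and pooled Acc aggregates the confusion counts of all
five validation folds; 96% is close to the Bayes optimum of this
generator (≈ 0.965 — negatives occasionally contain the consensus by
chance and are then indistinguishable). On real benchmark data accuracies
are substantially lower (≈ 77–90% in the literature).

The same pipeline is scriptable from the shell via the installed `exec`
script (`simulate`, `fit-encoder`, `encode`, `train`, `cv`, `predict`):

```sh
nppsvm=$(Rscript -e 'cat(file.path(find.package("nppsvm"), "exec", "nppsvm"))')
Rscript "$nppsvm" simulate --out-prefix demo --n-pos 200 --n-neg 200 --seed 1
Rscript "$nppsvm" cv --pos demo_pos.fasta --neg demo_neg.fasta \
    --k 10 --c-grid 1,32,1024 --gamma-grid 0.0078125,0.0625,0.5 \
    --seed 1 --out-json demo_cv.json
```

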