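Package: nppsvm
Title: N6-Methyladenosine Site Prediction from Nucleotide Pair Position
    Specificity Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies N6-methyladenosine (m6A) sites in fixed-length RNA
    sequence windows. Sequences are encoded with multi-interval nucleotide
    pair position specificity (NPPS) features: per-class positional
    frequency matrices of single nucleotides and gapped nucleotide pairs
    yield position-wise conditional probabilities under the methylated and
    unmethylated classes, and their difference is the feature vector. An
    RBF-kernel support vector machine, tuned by F-score-driven grid search,
    classifies the encoded windows. Includes stratified k-fold
    cross-validation and jackknife evaluation with leakage-free per-fold
    encoder refitting, the standard Sn/Sp/Acc/MCC and AUROC/AUPRC metrics,
    a synthetic motif-bearing window generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
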