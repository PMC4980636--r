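Package: m1Apred
Title: Sequence-Based Identification of N1-Methyladenosine Sites in RNA
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies N1-methyladenosine (m1A) sites in RNA from
    fixed-length, adenosine-centered sequence windows. Windows are encoded
    by nucleotide chemical properties (ring structure, hydrogen-bond
    strength, chemical functionality) together with cumulative nucleotide
    density, and classified with an RBF-kernel support vector machine whose
    cost and kernel width are selected by cross-validated grid search.
    Includes benchmark-dataset construction (redundancy reduction at a
    sequence-identity threshold, repeated balanced negative sampling),
    jackknife, k-fold and cross-dataset evaluation with sensitivity,
    specificity, accuracy, Matthews correlation coefficient, ROC and
    precision-recall analysis, a feature-ablation study, an optional
    pseudo-dinucleotide-composition encoder, and a synthetic window
    generator with controllable positional signal for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
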