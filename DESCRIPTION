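Package: mirtroncnn
Title: Nucleotide-Level Convolutional Networks for Pre-miRNA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human pre-miRNA hairpin sequences as canonical
    (Drosha-processed) miRNAs or mirtrons (splicing-derived) directly from
    the raw nucleotide sequence, with no hand-crafted features. Sequences
    are one-hot encoded (A, T/U, G, C) and zero-padded to a common length,
    then fed to shallow convolutional networks: four one-kernel variants
    (filter heights 3-6, 128 filters) and a mixed variant concatenating
    pooled features from all four heights (32 filters each). Includes the
    full training loop (cross-entropy, Adam, early stopping on held-out
    loss), confusion-matrix metrics (sensitivity, specificity, F1, MCC,
    accuracy) with mirtron as the positive class, a seeded synthetic
    sequence generator for end-to-end benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
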