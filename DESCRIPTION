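Package: acpflow
Title: Anticancer Peptide Classification with Attention-Augmented
    Convolution and Linear Flow-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end classifier for anticancer peptides (ACPs).
    Peptide sequences of 4-50 residues are one-hot encoded over the 20
    standard amino acids plus a pad symbol, passed through an
    attention-augmented convolution layer (a 1-D convolution branch
    concatenated with multi-head self-attention), a shrinking-kernel
    CNN fusion stack, a linear-complexity multi-head flow-attention
    mechanism built on flow-network conservation (sigmoid-mapped
    queries and keys with source-side competition and sink-side
    allocation), and an MLP softmax head.  Includes stratified
    splitting, five-fold cross-validation training with hand-derived
    backpropagation, the ACC/Sn/Sp/MCC/AUC metric suite, a synthetic
    motif-planting peptide generator for offline benchmarking, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
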