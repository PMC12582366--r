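Package: affinitylm
Title: Open-Chromatin DNA Language Models for Transcription Factor
    Binding Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a small Transformer-encoder DNA language model with
    rotary position embeddings, span-masked self-supervised pretraining on
    open-chromatin (ATAC-seq peak) sequence corpora, and parameter-efficient
    low-rank adaptation (LoRA) fine-tuning for transcription factor to DNA
    binding-affinity regression.  Ships the HT-SELEX protocol layer
    (per-cycle read counting, fold-enrichment relative-affinity estimation,
    affinity-binned fine-tune/validation/hold-out splitting), attention-based
    motif derivation with position frequency matrix export and
    score-correlation motif similarity, a synthetic planted-motif data
    generator for end-to-end validation, and PCC/AUROC evaluation tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
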