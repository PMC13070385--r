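Package: seq2track
Title: Sequence-to-Function Track Prediction with a Simplified Enformer and
    Cross-Species Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable implementation of the Enformer sequence-to-function
    architecture with ablation switches (attention-block output projection,
    final pointwise convolution, attention-block count), together with the full
    training methodology around it: one-hot windowed data preparation from
    FASTA and bedGraph at 128-bp bin resolution, Poisson negative log-likelihood
    training with AdamW and a linear warm-up/decay schedule, pretraining,
    head replacement, fine-tuning with optional trunk freezing, homology-aware
    train/validation/test splitting from PSL interval mappings, Pearson
    evaluation stratified by residual homology, and scripted experiment designs
    (architecture comparison, pretrain-versus-scratch-versus-freeze, and a
    track-count tradeoff sweep). A bundled synthetic benchmark generates
    desk-scale genomes, motif-driven Poisson coverage tracks, and cross-species
    task families with shared latent structure so every workflow is exercisable
    on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
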