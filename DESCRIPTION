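Package: sslabel
Title: Protein Secondary Structure Sequence Labeling with a Neural Linear-Chain CRF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Per-residue protein secondary structure prediction as neural
    sequence labeling. Fuses protein language model embeddings with token and
    sinusoidal positional sequence encoding, passes them through a
    Transformer/CNN/BiLSTM backbone to produce per-residue emission scores,
    and decodes with a linear-chain conditional random field trained by
    negative log-likelihood. Includes the Q3/Q8 accuracy and Sov
    segment-overlap evaluation metrics, a deterministic mock embedding
    provider, a synthetic Markov corpus generator for desk-scale training
    experiments, and a command-line interface for train/predict/evaluate.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
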