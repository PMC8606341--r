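Package: hnntm
Title: Hidden Neural Networks for Transmembrane Protein Topology Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Class hidden Markov models (CHMMs) for labeled biological
    sequences and their hybrid extension, hidden neural networks (HNNs), in
    which per-state emission probabilities are replaced by the outputs of
    small feed-forward networks over a windowed sequence context. Provides
    free-running and clamped forward-backward recursions with per-position
    scaling, labeled Baum-Welch estimation, discriminative conditional
    maximum likelihood training with RPROP, Viterbi and optimal-accuracy
    posterior label decoding, topology evaluation metrics (Q2, segment
    overlap, topology correctness, Matthews correlation), model-derived
    feature extraction with a logistic discriminator for membrane-protein
    detection, and seeded synthetic generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
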