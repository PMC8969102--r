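Package: demfusion
Title: Multimodal Transformer Fusion for Dementia Detection from Speech and Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting Alzheimer's dementia and predicting
    Mini-Mental State Examination (MMSE) scores from spontaneous speech and
    its transcript. Audio is rendered as a three-channel log-Mel /
    delta / delta-delta spectrogram image; CHAT transcripts are parsed and
    token-encoded; and three end-to-end trainable fusion architectures
    combine the modalities: co-attention over token and patch embeddings, a
    multimodal shifting gate that injects visual and acoustic information
    into word embeddings before a second text-encoder pass, and gated
    self-attention over the concatenated text and image sequence. Includes
    the full training protocol (Adam, reduce-on-plateau, early stopping,
    stratified splits, multi-run aggregation), classification and regression
    metrics, desk-scale randomly initialised encoders, and a synthetic
    corpus generator with a controllable group signal so every architecture
    can be exercised end-to-end without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
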