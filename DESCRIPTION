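Package: mieeg
Title: Motor-Imagery EEG Decoding with a Sparse-Attention Convolutional Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes motor-imagery intent from epoched multichannel EEG with a
    compact convolutional transformer. A multi-scale temporal/spatial
    convolutional front end extracts sensorimotor-rhythm features at three
    receptive-field scales, cross-branch additive recalibration with
    channel/spatial attention (CBAM) highlights informative maps, small-kernel
    position-aware enhancement adds a learnable positional code, and a sparse
    information-aggregation transformer attends over block-averaged keys/values
    plus the tokens of the top-k scoring blocks. Includes band-pass filtering,
    per-trial per-channel z-scoring, segmentation-and-reconstruction
    augmentation with bounded Gaussian noise, a within-session training
    protocol (Adam, cosine annealing, stratified splits), accuracy/Cohen's
    kappa/Wilcoxon evaluation, and a seeded synthetic sensorimotor-rhythm
    generator so the full pipeline runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
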