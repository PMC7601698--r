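Package: capgan
Title: Capsule-Network Generative Adversarial Synthesis of MR-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative adversarial synthesis of two-dimensional grayscale
    magnetic-resonance-like images using a capsule-network discriminator
    trained with least-squares adversarial losses. Provides the capsule
    primitives (squash nonlinearity, routing-by-agreement, margin loss), a
    transposed-convolution generator and capsule discriminator with
    hand-derived reverse-mode gradients and Adam optimisation, a
    KL-divergence image-quality metric built on HOG and LBP texture features
    with a probability-calibrated support vector machine, synthetic phantom
    and lesion-patch generators with the standard augmentation and
    stratified-split data pipeline, and a command-line interface for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
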