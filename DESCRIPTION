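Package: ffcnn
Title: Forward-Forward Training of Convolutional Neural Networks with
    Spatially-Extended Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Backpropagation-free training of convolutional neural networks
    with the Forward-Forward algorithm. Class labels are embedded across the
    whole image either as sinusoidal (Fourier) gray-value waves or as
    deterministic morphological transformation programs, so that every
    convolutional filter position can see the label. Each layer is trained
    on a local goodness objective (sum of squared rectified activations
    against a neuron-count threshold) using positive (correctly labeled) and
    negative (wrongly labeled) examples; no gradients cross layer
    boundaries. Inference is available via per-label goodness evaluation or
    a linear classifier head on the hidden activations, and the head weights
    yield class activation maps. Includes readers for MNIST IDX and CIFAR
    binary formats, a synthetic shape-image generator so everything runs
    without downloads, and greedy min-max-correlation label-set selection
    for many-class problems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
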