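Package: decifuse
Title: Multimodal EEG and Image Feature Fusion for Predicting Decision
    Correctness in Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting the correctness of human decisions in a
    six-alternative camouflaged visual-search task from multimodal data.
    Implements a synthetic study generator (epoched EEG with injected
    event-related potentials, textured stimulus images, segmentation-mask
    sets and behaviour tables), minimal EEG preprocessing, pointwise
    permutation tests with Bonferroni correction for ERP segment discovery,
    temporal EEG feature extraction with correlation pruning, formula-based
    image and mask-relational features, and a random-forest evaluation
    pipeline with importance-based top-k multimodal fusion benchmarked
    against behavioural reference accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
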