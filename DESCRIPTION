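Package: c2geeg
Title: Cluster-to-Global EEG Dimensional Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A local-global architecture for dimensional emotion decoding from
    multichannel EEG. Scalp electrodes are grouped into nine spatial clusters;
    each cluster is encoded by an EEG Deformer (shallow convolutional encoder,
    hierarchical coarse-to-fine transformer, and dense information
    purification), cluster features interact through bidirectional
    cross-attention, and the window sequence is integrated by a dilated
    temporal convolutional network before an MLP classifier. Includes the
    signal-conditioning chain (band-pass, re-referencing, stacked sparse
    autoencoder denoising, windowing, z-scoring), rating-to-class label maps,
    leave-one-subject-out and within-subject evaluation protocols, ablation
    variants, and a class-conditional synthetic EEG generator for end-to-end
    testing without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
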