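Package: hsqcsiam
Title: Siamese Convolutional Embeddings for 2D HSQC NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters structurally related natural products by their 1H-13C
    HSQC NMR spectra. Spectra are rasterized to binary images, embedded into a
    low-dimensional metric space by a weight-sharing (siamese) convolutional
    network trained with a margin-based contrastive loss, and compared by
    Euclidean distance for dereplication-style retrieval. Includes the full
    preprocessing chain (binarization, cross-shaped median filtering, peak-list
    rasterization), a synthetic HSQC corpus generator with family structure and
    spectral noise, Adagrad training with early stopping and k-fold
    cross-validation, and the retrieval evaluation suite (expanding-hypersphere
    precision-recall, accuracy versus radius, closest-retrieval curves with a
    most-occurring baseline, a linear PCA baseline, and a noise-robustness
    protocol).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
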