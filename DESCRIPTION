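Package: pathae
Title: Sparse Convolutional Autoencoders and Multi-Reduction Classifiers
    for Tissue-Scale Texture Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature learning and classification for large tissue-style
    raster images. Implements single-stage convolutional autoencoders with
    an information-entropy sparsity penalty on the encoding layer, greedy
    layer-wise (stacked) pre-training with frozen earlier stages, a
    reconstruction independent subspace analysis (RISA) layer with fixed
    group pooling, three classifier variants (direct, autoencoder-pretrained,
    RISA-pretrained) with softmax heads and confusion-matrix evaluation,
    and a tiled multi-reduction network that classifies large images from
    the spatial distribution of locally similar motifs. Ships a synthetic
    texture generator whose classes share a common bank of local motifs but
    differ only in the motifs' spatial point process, so that the effect of
    spatial context on classification is testable end to end without any
    external data. All numerics are plain R arrays with BLAS-backed
    im2col convolutions and Adam optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
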