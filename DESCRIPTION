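Package: wnet3d
Title: Self-Supervised 3D Nuclei Segmentation with a Dual U-Net and Soft
    Normalized Cuts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Self-supervised semantic and instance segmentation of nuclei in
    volumetric (light-sheet or confocal) microscopy. A dual 3D U-Net
    ("WNet3D") is trained without ground truth by minimising a weighted sum
    of a radius-limited 3D Soft Normalized Cuts loss on the encoder's soft
    class assignments and a reconstruction loss on the decoder output.
    Semantic probability maps are thresholded and converted to instance
    labels with Voronoi-Otsu labelling, connected components or a
    distance-transform watershed; label post-processing (ball closing,
    border-intensity merging, size filtering) and an instance-matching
    F1-versus-IoU evaluation suite are included, together with a seeded
    synthetic 3D nuclei generator and a command-line interface. The
    convolutional network, its backpropagation and all 3D labelling
    primitives are implemented in C++ for CPU use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
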