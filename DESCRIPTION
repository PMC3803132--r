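Package: spermwave
Title: Sperm Head Morphology Classification from Contour Waveforms and
    Gray-Level Features
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computer-assisted sperm-morphology diagnosis from grayscale
    micrographs. Segments sperm heads by gray-value thresholding, traces
    each head contour and transforms it into a one-dimensional waveform
    (centroid-to-edge distances or symmetric-pair distances), encodes
    waveforms with a circular rank-order binary code compared through a
    normalized rank-difference dissimilarity, extracts gray-level features
    along a square-spiral path from the head centre, and classifies heads
    with a weighted joint criterion and a feature-fused RBF support-vector
    machine. Includes K-nearest-neighbour and ellipse-ovality baselines and
    a synthetic micrograph generator with ground truth for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
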