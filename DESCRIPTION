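Package: persiseg
Title: Topology-Based Segmentation and 3D Reconstruction of Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of cell membranes and internal cavities in confocal
    volumes using persistent homology of cubical complexes. Each slice of a
    z-stack is analysed through sublevel- and superlevel-set filtrations of
    the intensity function; the most persistent one-dimensional homology
    classes are selected with an automatically chosen persistence threshold
    and turned into closed contours (the external membrane profile and the
    cavity outlines). Nested cycle representatives arising at saddle points
    are separated by a dilation-based splitting rule sized by the directed
    Hausdorff distance. Slice contours are then tiled into a triangulated
    surface under a maximum-distance association rule, smoothed with
    Taubin's method and remeshed to a uniform vertex density. A synthetic
    phantom generator with known ground truth supports end-to-end testing,
    and a command-line driver runs the full pipeline on multi-page TIFF
    stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
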