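Package: boxseg
Title: Interactive Bounding-Box Segmentation with Image-Specific Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Interactive two- and three-dimensional image segmentation from a
    user-supplied bounding box. A compact resolution-preserving dilated
    convolutional network proposes a binary foreground mask for the boxed
    region, and the mask is refined per test image by alternating exact
    graph-cut label updates of a contrast-sensitive conditional random field
    with uncertainty-weighted fine-tuning of the network's classifier layer,
    optionally guided by foreground and background scribbles. Because the
    network solves a generic extract-the-object-from-its-box problem, it can
    segment object classes that never appeared in training. Includes a
    synthetic multi-organ scene generator and a robot user so the whole
    pipeline, including behaviour on previously unseen object classes, can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
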