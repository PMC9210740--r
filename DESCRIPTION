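Package: plateletNano
Title: Nanoscale Protein Distribution Analysis and Classification of
    Platelets from STED Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the nanoscale distribution of immunostained
    proteins in super-resolution (STED) images of single platelets and to
    classify platelet ensembles by their co-culturing condition.  Each
    platelet image is reduced to five parameters: the number of protein
    clusters, their mean area, the first and second moments of the radial
    cluster distribution, and a structural-similarity (SSIM) score of a
    sparse dictionary reconstruction.  Kernel density estimates of these
    parameters per category drive a set-level probability-score classifier,
    bootstrap classification matrices, and a combined multi-protein
    probability model.  Includes a synthetic STED-like platelet image
    generator with known ground truth, Richardson-Lucy deconvolution,
    Fourier ring correlation resolution estimation, and a simulator of the
    streamlined acquisition logic (platelet detection and gradient
    autofocus).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
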