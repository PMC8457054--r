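Package: netskel
Title: Mesoscopic Network Analysis of Aggregated Particulate Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts single-voxel-thin network backbones from 3D image
    stacks (e.g. confocal microscopy of colloidal gels) or particle
    coordinate sets, converts them into graphs of nodes and links,
    cleans skeletonization artefacts, and quantifies mesoscopic network
    structure: node and link densities, link-length distributions and
    network tortuosity. Includes a synthetic phantom generator with
    known ground-truth topology for validation, a point-spread-function
    rendering model for coordinate data, and diagnostic image overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
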