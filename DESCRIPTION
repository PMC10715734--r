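Package: SynapseQuant
Title: Quantitative Analysis of B-Cell Immunological Synapse TIRF/IRM Time-Lapse Movies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify B-cell interactions with antigen-presenting
    planar lipid bilayers from multi-channel TIRF and IRM time-lapse
    microscopy. Segments the cell contact zone from IRM frames, classifies
    spreading-to-contraction transitions, detects inner F-actin foci by
    diameter, fold-intensity and edge-distance criteria, builds radial
    kymographs and extracts foci lifetimes and centripetal speeds, detects
    and tracks antigen (BCR-Fab') microclusters with a 16-level graded
    intensity threshold, and relates per-cluster signaling-channel staining
    to antigen cluster density. Includes a synthetic movie generator with
    exact ground truth so every analysis stage can be validated without
    microscope data, plus the nonparametric statistics and false-discovery
    rate corrections used in this type of study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization
RoxygenNote: 7.3.3
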