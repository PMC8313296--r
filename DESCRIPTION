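Package: osteoatlas
Title: Desk-Scale Osteocyte Connectomics: Phantom mSEM Mosaics, Cell
    Detection, Viability Classification and Network Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a desk-scale bone-connectomics workflow built
    around multibeam scanning electron microscopy (mSEM) mosaics of
    osteocyte networks. Generates seeded synthetic tile sets with known
    ground truth, stitches per-beam tiles into panoramas by recorded
    stage coordinates, detects osteocyte-like somata with a single-pass
    grid detector (normalized cross-correlation template bank, confidence
    thresholding, non-max suppression), classifies cells as viable or
    pyknotic by counting visible dendritic processes, builds spatial cell
    graphs and quantifies the loss of information transfer (global
    efficiency) under node removal, and exports navigable slippy-map tile
    pyramids with colour-coded cell pins.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
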