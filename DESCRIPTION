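Package: densamp
Title: Per-Atom Amplitude Analysis of Time-Resolved Difference Electron
    Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces three-dimensional crystallographic difference
    electron-density maps to one-dimensional per-atom dual-valued
    amplitude profiles by averaging, separately, the positive and
    negative difference density inside a sphere walked over every atom
    of a reference model. Provides Pearson correlation and block
    segmentation of amplitude profiles across a time series,
    nonnegative linear decomposition into intermediate populations,
    concentric-shell propagation analysis, calculation of theoretical
    difference maps from refined structure pairs with dummy-water
    relative scaling, and seeded synthetic map/structure generators
    with known ground truth. Reads and writes CCP4/MRC volumes and PDB
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
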