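Package: axonwrap
Title: Quantification of 3D Myelin Wrapping on Artificial Axon Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies three-dimensional myelin ensheathment of 3D-printed
    artificial-axon (AA) micropillar arrays from multichannel confocal
    z-stacks. Implements per-slice circumference-coverage scoring against a
    one-pixel pillar outline, contiguous sheath-segment extraction, the
    fully-wrapped classifier (>80% coverage over a contiguous >6 um axial
    segment) and the per-field myelin wrapping index (fully wrapped pillars
    per nucleus), together with pillar detection and z-linkage, nuclei
    counting, spherical Hertzian contact fitting of AFM force-indentation
    curves, plate-level aggregation with compound scoring, hit calling and
    ranking, and a synthetic-data generator that produces calibrated
    three-channel stacks, photomasks and force curves with exact ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Preprocessing
RoxygenNote: 7.3.3
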