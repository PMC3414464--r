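Package: nucmorph
Title: Nuclear Morphometric Analysis of Fluorescence Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nuclear morphology from fluorescence micrographs of
    DAPI- or Hoechst-stained nuclei. Segments nuclei, computes five shape
    descriptors (area, aspect, area box, radius ratio, roundness), combines
    four of them into the Nuclear Irregularity Index (NII), calibrates a
    reference model from curated normal nuclei and classifies every nucleus
    into one of seven phenotype categories (normal, irregular, large
    regular/irregular, small, small regular/irregular) indicative of
    interphase, mitotic-catastrophe-like irregularity, senescence, mitosis
    and apoptosis. Includes a synthetic micrograph generator with ground
    truth for validation, CSV/JSON/TIFF interchange and an area-versus-NII
    classification plot.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: CellBiology, Visualization, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
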