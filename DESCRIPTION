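Package: SRSflowSort
Type: Package
Title: Virtual Raman Image-Activated Cell Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A virtual instrument for stimulated Raman scattering (SRS)
    image-activated cell sorting. Simulates multicolor line-scan SRS flow
    imaging of Poisson particle streams with ground-truth labels, implements
    the real-time image-analysis chain (event detection, frame construction,
    square-pixel normalization, morphological cell masking, pseudo-inverse
    spectral unmixing, feature extraction and gating), models the on-chip
    dual-membrane push-pull sorter both analytically (a 32-scenario Poisson
    coincidence model of the throughput-purity trade-off) and by Monte-Carlo
    event-stream simulation, and computes sorting metrics (event rate,
    purity, yield).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, FlowCytometry, Software
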