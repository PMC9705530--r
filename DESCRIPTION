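Package: voltrace
Title: Volumetric Light-Sheet Calcium Imaging: Trace Extraction and
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for fast volumetric (4D) calcium-imaging
    movies acquired on static light-sheet microscopes. Provides artifact-aware
    preprocessing (median bleach correction and a spatial-Fourier
    temporal-variance filter that removes stripe artifacts and out-of-focus
    background), rigid 3D motion correction, a lightweight 3D constrained
    nonnegative matrix factorization that decomposes a movie into neuronal
    footprints, traces, background and noise (Y = AC + B + E), morphological
    and variance-based component filtering, Spearman-correlation functional
    connectivity graphs, segmentation scoring against consensus annotations,
    Gaussian-beam and point-spread-function characterization fits, and a fully
    seeded synthetic 4D movie generator with ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
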