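Package: sbemtools
Title: Stitching, Cubed Volume Access and Skeleton Consolidation for
    Serial Block-Face Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational building blocks for dense neuronal reconstruction
    from serial block-face scanning electron microscopy (SBEM) volumes:
    per-section tile registration by standardized FFT cross-correlation with
    global least-squares tile placement and Gaussian contrast normalization;
    a chunked ("cubed") multi-resolution volume store with dynamic
    neighborhood loading, persistent caching and trilinear oblique reslicing;
    reading and writing of NML skeleton annotations and NMX containers
    (including synapse triplets and soma outlines); CORE consolidation of
    redundant manual tracings with mismatch detection and error correction;
    and glomerular innervation morphometry with length-based reconstruction
    accuracy metrics (recall, precision, relative length error). Seeded
    synthetic-fixture generators provide textured tiles, tile grids,
    branching skeletons and convex regions with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
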