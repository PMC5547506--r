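Package: tricontact
Title: Fragment-Level 4C-seq Quantification and Tripartite Contact Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for viewpoint-based chromosome conformation capture
    (4C-seq) analysis at restriction-fragment resolution: in-silico double
    digestion (NlaIII/DpnII), read-to-fragment quantification with viewpoint
    exclusion, running-mean smoothing, bait-window scaling and power-law
    distance-decay correction; detection of three-way (tripartite) chromatin
    contacts from long single-end reads by ligation-junction splitting, with
    undigested-product filtering, positional deduplication and symmetric
    20-kb contact matrices; rank-based differential contact statistics; and
    coordinate liftover for engineered deletion and inversion alleles.
    Includes a synthetic proximity-ligation library generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    methods,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
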