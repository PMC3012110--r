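Package: chipconcord
Title: Cross-Platform Concordance Analysis of ChIP Binding-Site Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-validating genome-wide transcription-factor
    binding maps measured on two ChIP platforms: CARPET-style peak calling on
    replicate tiling-array tracks (quantile normalization, Tukey biweight
    summarization, percentile thresholding, probe-run grouping and merging),
    Poisson-window peak calling on read-coverage tracks, p-value stringency
    sweeps with inflection-point selection, TSS-relative peak annotation and
    density profiling, degenerate E-box (CANNTG) motif scanning and
    MDscan-style motif discovery, and hypergeometric gene-list enrichment
    with seeded random controls.  A synthetic-data module generates toy
    genomes, gene models, planted binding sites and replicate signal tracks
    with the statistical structure the analysis assumes, so the whole
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    limma,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    S4Vectors
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
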