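Package: tfcensus
Title: Transcription Factor Census, Co-Expression Modules and Hox
    Collinearity for Tunicate Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide transcription factor (TF)
    surveys in tunicates and other metazoans. Identifies and classifies TFs
    from Pfam DNA-binding-domain annotations (hmmscan per-domain tables)
    using per-family e-value thresholds and compound-domain rules (e.g.
    ZBTB = BTB + zf-C2H2); compares family repertoires across species
    (shared, exclusive, expanded and orphan families); detects co-expression
    modules over developmental stages with a weighted correlation network
    (soft-threshold adjacency, topological overlap, hierarchical module
    detection) implemented from first principles; analyses Hox-cluster
    temporal collinearity; and provides hypergeometric GO-term enrichment
    and comparative-Ct (2^-ddCt) arithmetic. Seeded generators produce every
    input format with known ground truth, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
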