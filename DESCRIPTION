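Package: pansynkit
Title: Pan-Genome Classification, Synteny Diversity and Centromere Size
    Analysis for Inbred Plant Genome Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gene-based pan-genome analysis of panels of
    chromosome-level genome assemblies: orthogroup fusion and
    split/merge-artifact correction from homology hits, core / softcore /
    dispensable / private gene-family classification, Monte Carlo and
    closed-form pan/core rarefaction curves, windowed synteny-diversity
    statistics projected onto a reference coordinate system, cross-accession
    structural-variant merging with breakpoint-distance clustering, and
    centromeric tandem-repeat annotation with depth-ratio repeat-length and
    assembly-completeness estimation.  Includes a synthetic pan-genome
    generator with known ground truth so every stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
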