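Package: mavemap
Title: Variant Effect Maps from Multiplexed Assays with Clinical Calibration
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed assays of variant effect (MAVE)
    based on TileSeq-style variant counting. Simulates saturation-mutagenesis
    libraries, selection experiments and sequencing count tables with known
    ground truth; turns pre/post-selection and wild-type-control counts into
    filtered, error-corrected, replicate-combined and rescaled functional
    scores; assembles position-by-residue variant effect maps with tolerance
    classification and map-level statistics; calibrates scores against
    reference variant sets into balanced precision-recall summaries,
    kernel-density log-likelihood ratios of pathogenicity and ACMG/AMP-style
    evidence strengths; and annotates maps with structure-derived (solvent
    accessibility, interface) and trajectory-derived (MSF, hydrogen-bond
    occupancy) features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
biocViews: Software, StatisticalMethod, Sequencing, VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
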