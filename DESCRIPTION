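Package: retentionshift
Title: Position-Specific Intron Retention and Histone-Mark Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intron retention from spliced RNA-seq alignments using
    a per-intron retention index (intron FPKM over the mean FPKM of its
    flanking exons), calls differential retention between conditions with
    read-support, coverage and expression filters, and tests whether
    up- and down-regulated retention events occupy different positions along
    the gene body (two-sample Kolmogorov-Smirnov test). Builds 500-bin
    input-calibrated ChIP-seq metagene profiles (100 upstream + 300 gene body
    + 100 downstream bins), detects promoter-proximal redistribution of
    histone marks such as H3K36me2/me3 with a sign-based half-body rule, and
    classifies genes by which marks shift. Predicts premature termination
    codons (stop more than 50 nt upstream of the last exon-exon junction) and
    nonsense-mediated decay candidates. Ships a seeded synthetic-data
    generator emulating the RNA-seq and ChIP-seq structure of such studies so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
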