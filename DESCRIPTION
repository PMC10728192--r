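Package: wormforge
Title: Design and Verification of Multiplexed CRISPR Stop-In Knockout Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building multiplexed CRISPR/Cas9 knockout libraries of
    large gene families (chemoreceptor and neuropeptide GPCRs in C. elegans):
    greedy protein-identity clustering of paralogs into co-editing groups,
    design of stop-in ssODN repair templates with 35-nt homology arms, a
    frameshifting deletion and a diagnostic restriction site, PCR/digest
    (RFLP) genotyping assay design, sequencing-based verification and
    classification of edited alleles, and the behavioral/imaging statistics
    used to call hits in phenotypic screens (chemotaxis indices, pathogen
    avoidance, photobleach-corrected calcium responses). A synthetic-data
    generator produces toy genomes, gene families with controlled identity,
    simulated editing outcomes and simulated screens so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
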