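Package: intronoscope
Title: Discovery and Characterization of Spliceosomal Introns and snRNAs
    in Intron-Poor Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for finding and characterizing the sparse spliceosomal
    introns of intron-poor eukaryotes such as diplomonads and parabasalids.
    Implements degenerate-consensus splice-site scanning with mismatches,
    genome-wide intron candidate discovery anchored on a fused branch-point
    plus 3' splice-site motif, open-reading-frame disruption assessment under
    the ciliate genetic code, triage of spliced-alignment junctions against
    reverse-transcriptase template-switching artifacts, constrained
    minimum-free-energy RNA secondary-structure prediction with a splice-site
    spatial-distance statistic, structured-motif search for U5 snRNA
    candidates and feature annotation of U2 candidates, intron
    positional-homology calls across orthologs, spliceosomal-protein census
    decision rules, and seeded synthetic-data generators with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, RNASecondaryStructure
RoxygenNote: 7.3.3
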