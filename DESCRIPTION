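Package: mitodelim
Title: Comparative Mitogenomics and Distance-Based Cryptic-Species Delimitation
Version: 0.1.0
Authors@R:
    person("Mito", "Delim", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: per-region nucleotide composition with AT/GC strand skew, relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial code,
    start/stop-codon classification including incomplete stops, pairwise
    genetic distances (uncorrected p and Kimura 2-parameter) with
    threshold-based single-linkage species delimitation, construction of
    codon-position-filtered (PCG12) supermatrices, neighbor-joining trees, and
    a seeded mitogenome simulator with full ground truth so every stage is
    testable without downloads. Includes GenBank flat-file and FASTA +
    feature-table readers and writers and a scriptable command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
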