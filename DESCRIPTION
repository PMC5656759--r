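Package: polycivir
Title: Comparative Genomics of Polycistronic Picorna-Like Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating and classifying polycistronic picorna-like
    RNA virus genomes (family Polycipiviridae). Enumerates open reading
    frames and infers the family-characteristic five-ORF genome layout with
    its UTR and intergenic statistics, scans the non-structural polyprotein
    for helicase, protease and RNA-dependent RNA polymerase motifs
    (including protease-triad and RdRp motif-VI variants), runs a
    reciprocal-best-hit discovery filter over translated searches, builds
    neighbor-joining trees from pairwise peptide identities and tests clade
    monophyly, classifies genomes into the three proposed genera, and
    summarizes read-mapping pileups into coverage profiles and
    synonymous/nonsynonymous SNP tallies. A seeded synthetic-genome module
    generates family-like genomes, evolved families, decoys and pileups
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    phangorn,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
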