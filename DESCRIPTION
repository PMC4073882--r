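Package: barcodeAudit
Title: Assessment of DNA Barcode-Based Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing the resolution and reliability of COI
    DNA-barcode species identification in taxonomically structured
    datasets such as marine copepods. Reads taxonomy-annotated barcode
    alignments, screens nuclear mitochondrial pseudogenes (numts) by
    reading-frame and divergence criteria, builds standard and
    unique-haplotype alignment variants, computes Kimura 2-parameter and
    p distances with pairwise deletion and overlap gates, summarises
    distances by taxonomic level with Mann-Whitney comparisons and
    barcode-gap reports, runs sliding-window nucleotide diversity,
    reconstructs neighbour-joining trees with bootstrap support,
    delimits putative species with a Poisson tree processes model,
    clusters molecular operational taxonomic units (MOTUs) by
    sequence-difference thresholds, performs best-close-match species
    assignment, quantifies MOTU/OTU concordance, and estimates PhiST
    between sample groups. A seeded simulator generates
    taxonomy-structured barcode datasets with known truth, including
    numt contaminants, truncated reads, zero-distance heterospecific
    pairs and deep conspecific splits, so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
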