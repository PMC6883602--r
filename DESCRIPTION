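Package: hoxclone
Title: Clone-Based Haplotyping, Recombinant Detection and Pseudogene
    Calling for Hox Amplicon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterising duplicated Hox gene copies in hybrid
    fish lineages from cloned PCR amplicon libraries. Collapses 20-30 clones
    per gene into distinct sequence types while filtering PCR and sequencing
    errors, transfers exon1-intron-exon2 annotation from reference haplotypes
    (with canonical GT..AG splice-site adjustment), detects mosaic
    (recombinant) clones by penalised minimum-mismatch dynamic programming
    over informative sites with breakpoint intervals, calls pseudogenes from
    premature in-frame stop codons, computes pairwise nucleotide and amino
    acid identity matrices over coding regions, and verifies gene-family
    clade structure with a neighbour-joining tree on amino acid p-distances.
    Includes a fully seeded simulator of parental haplotype panels and hybrid
    clone libraries with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: MAFFT (optional; joint alignment of mixed-length
    panels, with an internal centre-star fallback)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
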