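Package: ambigscan
Title: Ambiguity-Site Analysis of Heterogeneous Amplicon Consensus Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intragenomic and intergenomic sequence
    diversity recorded as IUPAC ambiguity codes in Sanger amplicon consensus
    sequences, as seen in yeasts whose rRNA repeat arrays and nuclear genes
    are not homogenised. Provides per-site variability censuses
    (dimorphic/trimorphic/tetramorphic site classification,
    transition/transversion typing, variability-block detection), haplotype
    enumeration with divergence bounds and minimum allele counts, OTU
    similarity-threshold splitting tests, codon-level
    synonymous/nonsynonymous classification of dimorphic sites, secondary
    structure (stem/loop, wobble-pairing) context annotation from
    dot-bracket input, binary fingerprint (RAPD/RFLP) distance and UPGMA
    clustering with Newick output, and a seeded simulator of chimeric
    genomes, repeat arrays evolving under homogenisation or birth-and-death
    dynamics, majority-peak consensus calling, and strain-structured band
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
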