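Package: plastomarker
Title: Comparative Plastome Analysis and Species-Diagnostic PCR Marker Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative analysis of chloroplast genomes (plastomes):
    quadripartite LSC/IRb/SSC/IRa partition detection and inverted-repeat junction
    comparison, SNP/indel extraction with transition/transversion classing, sliding-window
    and per-locus nucleotide diversity with mutational-hotspot ranking, microsatellite,
    dispersed and tandem repeat cataloguing, relative synonymous codon usage and
    Nei-Gojobori (1986) Ka/Ks selection classing, and discovery of species-diagnostic
    SNPs with allele-specific 3'-anchored PCR primer design validated by in-silico PCR.
    Includes a plastome family simulator with known truth tables so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
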