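Package: hybridcre
Title: Allele-Specific Analysis of Cis-Regulatory Elements in F1-Hybrid Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific analysis of cis-regulatory elements
    (CREs) in F1-hybrid genomes: pairing maternal and paternal alleles of
    summit-centered CREs, testing allelic imbalance in transcription-factor
    binding and chromatin signal with FDR control, scanning degenerate IUPAC
    k-mers and position weight matrices on both alleles to classify motif
    disruptions, quantifying positional SNP/indel enrichment around summits
    and motif anchors, and measuring hierarchical AP-1/TEAD co-binding.
    Includes a synthetic diploid fixture generator with known ground truth
    so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
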