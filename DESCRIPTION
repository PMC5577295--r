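Package: barcodegap
Title: DNA Barcode Gap Analysis, Species Identification and Diagnostic
    SNP Detection for Congeneric Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates short DNA barcodes (such as nuclear ribosomal ITS2)
    for species identification within a genus. Computes pairwise Kimura
    2-parameter distances with pairwise deletion, summarises inter- and
    intra-specific divergence (mean interspecific distance, theta prime,
    minimum interspecific distance, mean intraspecific distance, theta,
    coalescent depth), graphs and tests the barcoding gap (Wilcoxon
    two-sample and median tests), classifies queries by best-hit and
    nearest-distance rules with correct/ambiguous/incorrect outcomes,
    builds neighbor-joining and UPGMA trees with column-bootstrap support
    and tests species monophyly, detects species-diagnostic nucleotide
    positions and minimal multi-site signatures, and collapses aligned
    sequences into haplotypes. Includes a seeded synthetic-genus sequence
    simulator emulating a radiation of closely related species with shared
    haplotypes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
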