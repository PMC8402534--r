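Package: venus
Title: Neoantigen Prioritization by Weighted Rank-Sum Scoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate tumor neoantigens from somatic variant,
    gene expression, and MHC class-I binding prediction tables. Implements
    the VENUS RSUM score: candidate neo-peptides (25-mers centered on
    missense substitutions, and 9-mer-anchored 25-mers tailored from
    frameshift peptides) are ranked independently by mutation allele
    frequency, allele-corrected transcript abundance (corrTPM), and best
    predicted MHC-I IC50, and the three ranks are combined into a weighted
    rank sum with penalties for non-binders and for absent RNA coverage.
    Includes somatic-variant filtering, frameshift peptide construction and
    tailoring, validation metrics for ranked lists, comparator ranking
    strategies, and a seeded synthetic-cohort generator with implanted true
    neoantigens for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
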