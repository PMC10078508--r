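Package: mitochar
Title: Descriptive and Comparative Characterization of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize annotated circular mitochondrial genomes
    the way mitogenome announcement studies do: circular gene-layout
    accounting (sizes, intergenic spacers, gene overlaps, strand tallies,
    start/stop codon classification), base composition and AT/GC strand
    skews per gene class and codon position, codon usage and relative
    synonymous codon usage (RSCU) under mitochondrial genetic codes,
    per-gene nucleotide diversity and Nei-Gojobori Ka/Ks across ortholog
    panels, exact repeat detection in the A+T-rich control region, and
    preparation of concatenated protein-coding supermatrices with RAxML and
    NEXUS partition schemes plus a neighbor-joining sanity tree. A
    synthetic-genome and ortholog-divergence simulator makes every stage
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
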