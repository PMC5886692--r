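Package: hetmapr
Title: Heteroduplex DNA Tract Mapping in Mitotic Crossover Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps heteroduplex DNA (hetDNA) tracts in reciprocal mitotic
    crossover products from barcoded consensus amplicon reads. Starting from
    a pair of recombination substrate references sharing a dense set of
    engineered SNP markers, the package demultiplexes reads, clusters
    consensus species per product, diagnoses hetDNA where both parental
    alleles are present at a marker, segments genotype vectors into tracts,
    measures tract lengths to the most break-distal transition, classifies
    events by initiation mechanism (double-strand break, nick, or gap
    patterns), and infers the initiating-lesion position for spontaneous
    events. A strand-resolved simulator of the underlying repair mechanisms
    provides ground truth for every stage, and a statistics layer supplies
    median tract summaries, contingency tests, and Lea-Coulson
    fluctuation-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
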