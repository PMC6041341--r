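Package: genelossr
Title: Gene-Family Loss, Expression Specificity and Genome-Survey Analysis
    for Parasitic Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics analysis of regressive genome
    evolution in heterotrophic plants. Identifies conserved orthogroups from
    orthogroup-by-species gene-count tables, calls and partitions gene losses
    between target species, summarises family-size deviation with the F-index
    statistic, classifies principally expressed tissues (PETs) and genes
    (PEGs) from expression matrices, detects frameshift and premature-stop
    lesions in candidate coding sequences against intact references, estimates
    genome size and repeat content from k-mer depth histograms, and ships
    seeded synthetic-data generators with planted ground truth plus an
    end-to-end pipeline driver.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
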