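Package: gutbaseline
Title: Healthy Gut Microbiome Baseline Profiling and Clinical Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for building a healthy human gut
    microbiome baseline: construction of a blacklist-filtered nucleotide
    reference database from taxonomy dump tables, FASTQ read quality
    control, a subsampling taxonomic census with curation rules, best-match
    read-to-organism abundance profiling with taxonomic rank roll-ups,
    extraction and tagging of metagenomic dark-matter contigs, a versioned
    organism knowledgebase with representative-proteome-group expansion,
    cosine-similarity correlation of nutrient features with organism
    abundances, and a standardized three-domain fecal biome report with
    cohort reference ranges. Includes seed-deterministic synthetic-data
    generators (toy taxonomies, genomes, reads with a substitution error
    model, planted dark matter, and feature tables with planted
    correlations) so the whole pipeline is testable without downloads.
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
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
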