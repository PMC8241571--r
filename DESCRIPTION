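Package: phagetools
Title: Viral Genome Discovery, Quality Control and Clustering from Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for cataloguing bacteriophage and other viral
    genomes assembled from bulk metagenomes. Implements multi-signature viral
    contig classification with a benchmark-driven cutoff search, terminal-repeat
    and large-repeat genome quality control, detection of alternative genetic
    codes from coding-potential comparisons, greedy ANI/AF clustering into
    species-level vOTUs, Markov clustering of amino-acid-identity gene-sharing
    graphs into genus- and family-level groups, bit-score-weighted consensus
    taxonomy, CRISPR-spacer and genome-match host prediction, and phylogenetic
    utilities (marker concatenation, gap trimming, phylogenetic diversity,
    core-SNP matrices). Ships seeded synthetic-data generators so the whole
    pipeline is testable end-to-end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
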