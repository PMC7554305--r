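Package: mvocphylo
Title: Phylogenetic Signal Analysis of Microbial Volatilome Presence/Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and phylogenetic analysis of binary (presence/absence)
    microbial volatile organic compound profiles at the genus level. Provides
    ingestion and genus-level agglomeration of volatile observation records,
    prevalence summaries, binary (Jaccard) distance ordination and one-factor
    PERMANOVA across taxonomic ranks, the Fritz-Purvis D statistic for binary
    traits with tip-permutation and Brownian-threshold null distributions,
    conservation classification of volatiles by producing superkingdom,
    richness and frequency comparison with the Mann-Whitney U test, exclusive
    (UpSet-style) set-intersection counting, an iTOL binary-dataset annotation
    exporter, and a synthetic-data generator (Yule trees plus clade-conserved,
    Brownian-threshold, and phylogenetically random binary traits) so that
    every pipeline stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
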