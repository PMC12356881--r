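Package: mqtlscore
Title: LD-Adjusted Methylation QTL Genotypic Scores for Disease Association and Colocalisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds locus-specific genotypic scores that predict DNA methylation
    at CpG probes from mQTL summary statistics, adjusting the effect-size
    weights for linkage disequilibrium with a reference-panel correlation
    matrix. Partitions per-probe summary statistics into trait-associated
    regions, applies standard variant and sample quality control, tests the
    resulting scores against case-control status and survival or recurrence
    outcomes with Benjamini-Hochberg false-discovery-rate control, and runs
    approximate-Bayes-factor colocalisation of mQTL and disease GWAS signals.
    Ships a synthetic-data generator with LD-block genotype structure and
    planted effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
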