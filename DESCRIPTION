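Package: cytonuclear
Title: Chromosomal Distribution Analysis of Cytonuclear Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether nuclear genes that interact with mitochondria
    (N-mt, GO:0005739) or chloroplasts (N-cp, GO:0009507) are over- or
    underrepresented on sex chromosomes relative to autosomes. Reads
    per-gene Gene Ontology annotation tables in the style of a Blast2GO
    export, tabulates gene counts by gene set (autosomal, X-linked,
    X-hemizygous), estimates observed-to-expected ratios with percentile
    bootstrap confidence intervals, tests representation differences with
    the Freeman-Halton exact test on 2xK contingency tables by full
    fixed-margin enumeration, and estimates the power of that test to
    detect differences in category proportions by Monte-Carlo simulation.
    A synthetic-data generator produces annotation tables with known
    enrichment effects for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
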