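Package: crossqtl
Title: QTL Mapping in F2 Line Crosses by Haley-Knott Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for quantitative trait locus (QTL)
    mapping in F2 intercrosses between two divergent outbred founder lines.
    Provides a synthetic-cross generator with known ground truth, genotype
    quality control for pedigreed SNP data, multipoint line-origin probability
    inference by a hidden Markov model, one-dimensional Haley-Knott genome
    scans with iterative cofactor selection, an exhaustive two-locus epistasis
    scan, permutation-based genome-wide significance thresholds, and a
    region-placement permutation test for pathway-gene enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
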