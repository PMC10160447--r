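Package: bsaqtl
Title: Bulked-Segregant SNP-Index Mapping of a Dominant Fruit-Colour Locus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for QTL-seq style bulked-segregant
    mapping of a single dominant locus in a biparental cross. Simulates F2 and
    backcross populations, phenotype-selected bulks and pooled short-read allele
    depths; computes per-site SNP-index and delta-SNP-index tracks with
    sliding-window means and threshold-based candidate-region calling; performs
    Mendelian segregation chi-square tests; narrows the causal interval from
    recombinant marker genotypes with co-dominant InDel marker selection; and
    evaluates spectrophotometric chlorophyll/carotenoid content and the
    colorimetric citrus colour index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
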