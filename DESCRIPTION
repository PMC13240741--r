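Package: haplopair
Title: Allele Identification and Allele-Specific Expression from
    Haplotype-Resolved Diploid Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies true allele pairs between the two haplotypes of a
    diploid genome assembly and classifies allele-specific expression.
    Candidate pairs are found by reciprocal-best-hit protein homology
    restricted to corresponding chromosomes, chained into colinear synteny
    blocks, scored for synonymous and non-synonymous divergence (Ka/Ks,
    Nei-Gojobori with Jukes-Cantor correction), and filtered by a dual
    statistical layer: an outlier rule on Ks (3-sigma or Tukey fences)
    followed by a block-slope filter. Allele-specific expression is
    classified per condition from replicate count matrices with a
    negative-binomial Wald test into five categories. A truth-labelled
    synthetic-diploid simulator supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
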