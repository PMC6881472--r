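Package: editevo
Title: Evolutionary Analysis of A-to-I RNA Recoding in Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether abundant nonsynonymous A-to-I (read as
    A-to-G) RNA editing is adaptive or merely harm-permitting. Classifies
    edited adenosines against ancestral amino-acid states reconstructed on a
    species tree (synonymous, restorative, diversifying), compares editing
    frequencies and levels between categories, computes nucleotide-change-
    class-restricted dN/dS with a gene-level bootstrap, estimates the
    adaptive fraction of diversifying editing from level-binned frequency
    excesses, and analyses editing shared across species including its
    replacement by genomic substitutions. A synthetic-data generator
    implementing the harm-permitting substitution model provides a
    ground-truth test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
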