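Package: antherlipids
Title: Heat-Stress Remodeling Analysis of Plant Anther Lipidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrospray-ionization lipidomics of
    reproductive plant tissue under contrasting temperature treatments:
    shorthand lipid nomenclature parsing, limit-of-detection and
    quality-control-pool coefficient-of-variation filtering, percent-of-total
    normalization, headgroup-class and molecular-species composition,
    amount-weighted unsaturation indices, fatty-acid decomposition and fold
    changes, least-squares cell means with Fisher's LSD lettering, two-class
    partial least squares discriminant analysis with variable importance in
    projection scores, Spearman single-linkage co-occurrence grouping with
    Newick export, and delta-delta-Ct relative expression.  Includes a
    seeded synthetic-study generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    emmeans,
    igraph,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
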