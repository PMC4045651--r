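Package: duoburden
Title: Rare-Variant Candidate-Gene Burden Analysis for Mother-Infant Exome Duos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for germline rare-variant candidate-gene enrichment analysis
    in mother-infant exome duos and unaffected controls. Implements the
    quality/rarity/consequence filtering cascade for annotated exome variants,
    exact hypergeometric and permutation tests of candidate gene-set
    enrichment, maternal attribution and presence-based compound-heterozygote
    calling in duos, gene-by-individual variability matrices with top-gene
    ranking, gene-size correlation checks, and a fully parameterised synthetic
    duo-cohort simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
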