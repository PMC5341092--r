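Package: testevol
Title: Essentiality and Sequence Evolution of Testis-Expressed Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating two kinds of gene essentiality --
    prepubertal lethality and male sub-/infertility, derived from mouse
    knockout phenotype annotations -- to pairwise human-mouse dN/dS and to
    three evolutionary-constraint proxies: protein-protein interaction
    node degree, the tissue-specificity index tau, and GO-slim
    biological-process multifunctionality. Includes a knockout-phenotype
    essentiality classifier over the Mammalian Phenotype ontology, PPI
    network cleanup and degree extraction, tau computation from FPKM
    matrices, map2slim-style GO-slim counting, first-principles
    implementations of the rank-based and exact statistics used
    (Spearman and partial Spearman correlations, Kruskal-Wallis,
    Mann-Whitney U, Pearson chi-squared, Fisher/Freeman-Halton exact
    tests, Holm adjustment, bootstrap median confidence intervals), and a
    synthetic-data generator that emulates the study's statistical
    structure so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
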