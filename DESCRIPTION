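Package: ontoexpress
Title: Ontology-Driven Expression Calls, Scores and Anatomical
    Enrichment for Bulk and Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates bulk and pseudo-bulked droplet single-cell
    RNA-seq abundance data into qualitative present/absent expression
    calls and quantitative 0-100 expression scores over a graph of
    ontology-composed annotation conditions. Present/absent calls test
    each gene against an empirical null distribution built from a
    stringently selected set of intergenic regions; per-sample p-values
    and fractional expression ranks are propagated and integrated along
    a condition graph built from anatomy, cell-type and
    developmental-stage ontologies plus sex and strain vocabularies.
    Also provides ontology-reasoned annotation queries, taxon-constraint
    filtering for multispecies ontologies, topGO-style (elim) enrichment
    of anatomical and cell-type terms in gene lists, a synthetic-data
    generator with known ground truth, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
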