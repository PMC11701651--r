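# Term-gene mapping from calls, the exact hypergeometric test, and
# enrichment with elim decorrelation.

# Synthetic ovary fixture emulating a fly follicle-cell enrichment: two
# follicle leaf terms under 'ovary', plus a distractor organ, all under
# one root (constructed fixture, not database content).
ovary_ontology <- function() {
  parse_obo(obo_lines(
    "format-version: 1.2",
    term_stanza("XAO:0000000", "anatomical entity"),
    term_stanza("UBERON:0000992", "ovary", is_a = "XAO:0000000"),
    term_stanza("FBbt:00005402", "oocyte associated follicle cell",
                part_of = "UBERON:0000992"),
    term_stanza("FBbt:00004908", "nurse follicle cell",
                part_of = "UBERON:0000992"),
    term_stanza("UBERON:0000955", "brain", is_a = "XAO:0000000"),
    term_stanza("FBbt:00005106", "neuron", part_of = "UBERON:0000955")
  ))
}

ovary_term_map <- function() {
  # 8 fertility genes split over the two follicle leaves, 22 background
  # genes spread over brain/neuron; ovary and root inherit by propagation
  genes <- sprintf("FG%02d", 1:30)
  calls <- data.frame(
    gene_id = genes,
    anat_id = c(rep("FBbt:00005402", 4), rep("FBbt:00004908", 4),
                rep("FBbt:00005106", 12), rep("UBERON:0000955", 10)),
    cell_type_id = "XAO:0000000",
    state = "present",
    stringsAsFactors = FALSE
  )
  map_genes_to_terms(calls, ovary_ontology())
}

test_that("map_genes_to_terms propagates genes to every ancestor", {
  onto <- ovary_ontology()
  calls <- data.frame(gene_id = c("g1", "g2"),
                      anat_id = c("FBbt:00005402", "UBERON:0000955"),
                      cell_type_id = c("XAO:0000000", "XAO:0000000"),
                      state = c("present", "absent"))
  tm <- map_genes_to_terms(calls, onto)
  expect_identical(tm[["FBbt:00005402"]], "g1")
  expect_identical(tm[["UBERON:0000992"]], "g1")   # leaf -> ancestors
  expect_identical(tm[["XAO:0000000"]], "g1")
  expect_false("UBERON:0000955" %in% names(tm))    # absent calls ignored

  expect_length(map_genes_to_terms(calls[calls$state == "absent", ], onto), 0L)

  # propagation invariant: a term's gene set contains the union of its
  # descendants' gene sets (closure oracle via descendants())
  tm2 <- ovary_term_map()
  for (t in names(tm2)) {
    below <- unlist(lapply(descendants(onto, t), function(d) tm2[[d]]))
    expect_true(all(below %in% tm2[[t]]))
  }
})

test_that("hypergeom_test is exact against exhaustive enumeration", {
  # k = n = K = 2, N = 4: 1 of the 6 possible draws has both annotated
  expect_equal(hypergeom_test(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_test(0, 3, 5, 10), 1)
  # symmetry in n and K
  expect_equal(hypergeom_test(3, 5, 7, 12), hypergeom_test(3, 7, 5, 12))
  set.seed(51)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_test(k, n, K, N), oracle_hyper(k, n, K, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_test(3, 2, 5, 10), class = "oe_invalid_counts")
  expect_error(hypergeom_test(1, 5, 11, 10), class = "oe_invalid_counts")
})

test_that("topanat classic: foreground == background gives p = 1 everywhere", {
  tm <- ovary_term_map()
  onto <- ovary_ontology()
  bg <- sort(unique(unlist(tm)))
  res <- topanat(bg, bg, tm, onto, method = "classic")
  expect_true(all(res$p == 1))
  expect_true(all(res$fdr >= res$p))
})

test_that("topanat finds a concentrated leaf and elim demotes its ancestors", {
  tm <- ovary_term_map()
  onto <- ovary_ontology()
  fg <- sprintf("FG%02d", 1:8)   # exactly the two follicle leaves

  classic <- topanat(fg, term_map = tm, ontology = onto, method = "classic")
  elim <- topanat(fg, term_map = tm, ontology = onto, method = "elim")

  # under elim the two follicle leaves outrank 'ovary'
  expect_setequal(elim$term[1:2], c("FBbt:00005402", "FBbt:00004908"))
  expect_gt(elim$p[elim$term == "UBERON:0000992"],
            max(elim$p[1:2]))
  # under classic, 'ovary' (k = 8, K = 8) is the single most significant
  expect_identical(classic$term[1L], "UBERON:0000992")

  # elim == classic for terms with no significant descendant
  for (t in c("FBbt:00005402", "FBbt:00004908", "FBbt:00005106")) {
    expect_equal(elim$p[elim$term == t], classic$p[classic$term == t])
  }

  # BH is monotone: sorting by p equals sorting by fdr
  expect_identical(order(classic$p, classic$term),
                   order(classic$fdr, classic$p, classic$term))

  # results sorted by p then term id
  expect_identical(elim$p, sort(elim$p))
})

test_that("topanat guards its inputs", {
  tm <- ovary_term_map()
  onto <- ovary_ontology()
  expect_error(topanat(character(0), term_map = tm, ontology = onto),
               class = "oe_empty_foreground")
  expect_warning(
    topanat(c("FG01", "NOT_A_GENE"), term_map = tm, ontology = onto),
    "not in background")
  expect_error(
    topanat("NOT_A_GENE", term_map = tm, ontology = onto, strict = TRUE),
    class = "oe_foreground_not_in_background")
  # K < 2 terms are skipped and counted
  tm_small <- structure(list("T:1" = "FG01",
                             "T:2" = c("FG01", "FG02", "FG03")),
                        class = "term_gene_map")
  onto_small <- parse_obo(obo_lines(term_stanza("T:2"),
                                    term_stanza("T:1", is_a = "T:2")))
  res <- topanat("FG01", term_map = tm_small, ontology = onto_small)
  expect_identical(res$term, "T:2")
  expect_identical(attr(res, "n_skipped"), 1L)
})
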