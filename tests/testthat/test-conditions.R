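# Condition post-composition, the condition graph and annotation queries.

test_that("compose_condition validates terms and keeps axes separate", {
  axes <- retina_axes()
  cond <- compose_condition(axes, anat = "UBERON:0000966",
                            cell_type = "CL:0000748",
                            stage = "ST:0000002", species = "9606")
  expect_s3_class(cond, "condition")
  expect_identical(cond$anat, "UBERON:0000966")
  expect_identical(cond$cell_type, "CL:0000748")
  expect_identical(cond$sex, "any sex")        # vocabulary root default
  expect_identical(cond$strain, "wild type")

  root_cond <- compose_condition(axes, species = "9606")
  expect_identical(root_cond$anat, "UBERON:0001062")
  expect_identical(root_cond$cell_type, "CL:0000000")

  expect_error(compose_condition(axes, anat = "UBERON:9999999",
                                 species = "9606"),
               class = "oe_unknown_term")
  tc <- taxon_constraints(
    setdiff(c(axes$ont$anat$ids, axes$ont$cell_type$ids, axes$ont$stage$ids),
            "CL:0000748"),
    "9606", TRUE)
  expect_error(
    compose_condition(axes, anat = "UBERON:0000966",
                      cell_type = "CL:0000748", species = "9606", tc = tc),
    class = "oe_term_not_in_species"
  )
})

test_that("collapse_condition is idempotent and equalizes dropped axes", {
  axes <- retina_axes()
  c1 <- compose_condition(axes, anat = "UBERON:0000966",
                          cell_type = "CL:0000561", stage = "ST:0000002",
                          sex = "female", species = "9606")
  c2 <- compose_condition(axes, anat = "UBERON:0000966",
                          cell_type = "CL:0000561", stage = "ST:0000002",
                          sex = "male", species = "9606")
  k1 <- collapse_condition(axes, c1, c("anat", "stage"))
  expect_identical(k1$anat, "UBERON:0000966")
  expect_identical(k1$cell_type, "CL:0000000")
  expect_identical(k1$sex, "any sex")
  # idempotent
  expect_identical(collapse_condition(axes, k1, c("anat", "stage")), k1)
  # identity when keeping all axes
  expect_identical(collapse_condition(axes, c1, ontoexpress:::OE_AXES), c1)
  # two conditions differing only in sex collapse to the same condition
  expect_identical(condition_key(collapse_condition(axes, c1, c("anat", "stage"))),
                   condition_key(collapse_condition(axes, c2, c("anat", "stage"))))
})

test_that("condition_ancestors matches the per-axis enumeration oracle", {
  axes <- retina_axes()
  # per-axis strict ancestor counts: anat retina -> 1 (root); cell
  # amacrine -> 2 (interneuron + cell root, which is also the sentinel);
  # stage adult -> 1; sex female -> 1; strain wild type (root) -> 0
  cond <- compose_condition(axes, anat = "UBERON:0000966",
                            cell_type = "CL:0000561", stage = "ST:0000002",
                            sex = "female", species = "9606")
  anc <- condition_ancestors(axes, cond)
  n_axis <- c(1L, 2L, 1L, 1L, 0L)
  expect_length(anc, prod(1L + n_axis) - 1L)
  # every ancestor is ancestor-or-equal axis-wise, never equal overall
  keys <- vapply(anc, condition_key, "")
  expect_false(condition_key(cond) %in% keys)
  expect_false(anyDuplicated(keys) > 0)
  for (a in anc) expect_true(is_condition_ancestor(axes, a, cond))
  # the species root condition has no ancestors
  root_cond <- compose_condition(axes, species = "9606")
  expect_length(condition_ancestors(axes, root_cond), 0L)
})

test_that("ancestor counts follow the product formula on random DAG axes", {
  set.seed(21)
  d1 <- random_dag_edges(15L, 0.15); d2 <- random_dag_edges(12L, 0.2)
  onto1 <- .new_ontology_for_test(d1); onto2 <- .new_ontology_for_test(d2)
  stage <- parse_obo(tiny_stage_obo())
  axes <- condition_axes(onto1, stage, vocabulary("any sex", "male"),
                         vocabulary("wild type", "x"), cell_type = onto2,
                         anat_root = d1$ids[1L], cell_root = d2$ids[1L])
  R1 <- closure_matrix(d1$ids, d1$edges)
  R2 <- closure_matrix(d2$ids, d2$edges)
  for (i in 1:10) {
    a <- sample(d1$ids, 1L); ct <- sample(d2$ids, 1L)
    cond <- structure(list(anat = a, cell_type = ct, stage = "ST:0000001",
                           sex = "male", strain = "wild type",
                           species = "1"),
                      class = "condition")
    # oracle per-axis counts from the closure matrix (+ root sentinel if
    # not already reachable / not the value itself)
    n_a <- length(union(oracle_ancestors(R1, a), setdiff(d1$ids[1L], a)))
    n_c <- length(union(oracle_ancestors(R2, ct), setdiff(d2$ids[1L], ct)))
    expected <- (1L + n_a) * (1L + n_c) * 2L * 2L * 1L - 1L
    expect_length(condition_ancestors(axes, cond), expected)
  }
})

test_that("the condition graph reproduces the product order", {
  axes <- retina_axes()
  ann <- retina_annotations()
  g <- build_condition_graph(axes, ann)
  expect_s3_class(g, "condition_graph")
  expect_true(all(g$annotated %in% g$nodes$key))
  # edge-based reachability == axis-wise ancestor predicate, brute force
  ig <- igraph::graph_from_data_frame(g$edges[, c("child", "parent")],
                                      vertices = g$nodes$key)
  conds <- lapply(seq_len(nrow(g$nodes)), function(i) {
    structure(as.list(g$nodes[i, c("anat", "cell_type", "stage", "sex",
                                   "strain", "species")]),
              class = "condition")
  })
  names(conds) <- g$nodes$key
  probe <- sample(g$nodes$key, min(25L, nrow(g$nodes)))
  for (k in probe) {
    reach <- names(igraph::subcomponent(ig, k, mode = "out"))
    for (k2 in sample(g$nodes$key, 10L)) {
      expect_identical(
        k2 %in% reach,
        is_condition_ancestor(axes, conds[[k2]], conds[[k]])
      )
    }
  }
  # annotated conditions deduplicate; shared ancestors appear once
  expect_false(anyDuplicated(g$nodes$key) > 0)
})

test_that("a single root annotation yields a one-node, zero-edge graph", {
  axes <- retina_axes()
  cond <- compose_condition(axes, species = "9606")
  g <- single_condition_graph(axes, cond)
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(nrow(g$edges), 0L)
})

test_that("the node cap trips loudly", {
  axes <- retina_axes()
  ann <- retina_annotations()
  expect_error(build_condition_graph(axes, ann, max_nodes = 3),
               class = "oe_condition_explosion")
})

test_that("query_annotations reasons over the ontology", {
  axes <- retina_axes()
  ann <- retina_annotations()
  expect_error(query_annotations(ann, axes), class = "oe_no_species_or_experiment")

  # child-inclusive interneuron query retrieves exactly the three subtypes
  hits <- query_annotations(ann, axes, species = "9606",
                            cell_type = "CL:0000099",
                            include_children = c(anat = FALSE,
                                                 cell_type = TRUE,
                                                 stage = FALSE))
  expect_identical(nrow(hits), 3L)
  expect_identical(sort(unique(hits$cell_type_id)),
                   c("CL:0000561", "CL:0000745", "CL:0000748"))
  expect_identical(attr(hits, "observed")$cell_type,
                   c("CL:0000561", "CL:0000745", "CL:0000748"))

  # without child expansion the parent term matches nothing
  none <- query_annotations(ann, axes, species = "9606",
                            cell_type = "CL:0000099")
  expect_identical(nrow(none), 0L)

  # child-inclusive results are a superset of exact-match results
  exact <- query_annotations(ann, axes, species = "9606",
                             cell_type = c("CL:0000561", "CL:0000066"))
  expanded <- query_annotations(ann, axes, species = "9606",
                                cell_type = c("CL:0000561", "CL:0000066"),
                                include_children = c(anat = FALSE,
                                                     cell_type = TRUE,
                                                     stage = FALSE))
  expect_true(all(exact$library_id %in% expanded$library_id))

  # empty filters with species: everything
  all_h <- query_annotations(ann, axes, species = "9606")
  expect_identical(nrow(all_h), nrow(ann))
  # axes are ANDed
  both <- query_annotations(ann, axes, species = "9606",
                            anat = "UBERON:0000966",
                            cell_type = "CL:0000066")
  expect_identical(nrow(both), 0L)
})
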