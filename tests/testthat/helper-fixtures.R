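# Fixtures built in code and independent brute-force oracles.

# ---- OBO fixtures ----

obo_lines <- function(...) paste(c(...), collapse = "\n")

term_stanza <- function(id, name = id, is_a = character(0),
                        part_of = character(0), obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    if (length(is_a)) paste0("is_a: ", is_a),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    if (obsolete) "is_obsolete: true")
}

# Cell-type fixture around the interneuron subtree: CL:0000099
# 'interneuron' with the three subtypes used in retina annotations, plus
# two unrelated cell types, all under a common 'cell' root.
interneuron_cell_obo <- function() {
  obo_lines(
    "format-version: 1.2",
    term_stanza("CL:0000000", "cell"),
    term_stanza("CL:0000099", "interneuron", is_a = "CL:0000000"),
    term_stanza("CL:0000561", "amacrine cell", is_a = "CL:0000099"),
    term_stanza("CL:0000745", "retina horizontal cell", is_a = "CL:0000099"),
    term_stanza("CL:0000748", "retinal bipolar neuron", is_a = "CL:0000099"),
    term_stanza("CL:0000066", "epithelial cell", is_a = "CL:0000000"),
    term_stanza("CL:0000037", "hematopoietic stem cell", is_a = "CL:0000000")
  )
}

tiny_anatomy_obo <- function() {
  obo_lines(
    "format-version: 1.2",
    term_stanza("UBERON:0001062", "anatomical entity"),
    term_stanza("UBERON:0000955", "brain", is_a = "UBERON:0001062"),
    term_stanza("UBERON:0000966", "retina", part_of = "UBERON:0001062")
  )
}

tiny_stage_obo <- function() {
  obo_lines(
    "format-version: 1.2",
    term_stanza("ST:0000000", "life cycle"),
    term_stanza("ST:0000001", "embryo", is_a = "ST:0000000"),
    term_stanza("ST:0000002", "adult", is_a = "ST:0000000")
  )
}

retina_axes <- function() {
  condition_axes(
    anatomy = parse_obo(tiny_anatomy_obo()),
    stage = parse_obo(tiny_stage_obo()),
    sex = vocabulary("any sex", c("female", "male")),
    strain = vocabulary("wild type", c("C57BL/6")),
    cell_type = parse_obo(interneuron_cell_obo())
  )
}

# Five human annotations: the three interneuron subtypes plus two
# distractor cell types.
retina_annotations <- function() {
  ct <- c("CL:0000561", "CL:0000745", "CL:0000748",
          "CL:0000066", "CL:0000037")
  data.frame(
    experiment_id = "EXPFIX1",
    library_id = paste0("LIB", seq_along(ct), "#c1"),
    species_id = "9606",
    anat_id = c(rep("UBERON:0000966", 3L), "UBERON:0000955", "UBERON:0000955"),
    cell_type_id = ct,
    stage_id = "ST:0000002",
    sex = "any sex",
    strain = "wild type",
    free_text_label = paste("author label", seq_along(ct)),
    data_type = "sc_droplet",
    integrated = TRUE,
    stringsAsFactors = FALSE
  )
}

# ---- random-DAG generator and closure oracle ----

# Random DAG on n nodes: edges only from higher to lower index, so
# acyclicity holds by construction.
random_dag_edges <- function(n, p = 0.08, relations = c("is_a", "part_of")) {
  ids <- sprintf("T:%04d", seq_len(n))
  child <- character(0); parent <- character(0); rel <- character(0)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (stats::runif(1) < p) {
        child <- c(child, ids[j]); parent <- c(parent, ids[i])
        rel <- c(rel, sample(relations, 1L))
      }
    }
  }
  list(ids = ids,
       edges = data.frame(child = child, parent = parent, relation = rel))
}

.new_ontology_for_test <- function(d) {
  ontoexpress:::.new_ontology(d$ids, d$ids, d$edges)
}

random_dag_ontology <- function(n, p = 0.08) {
  d <- random_dag_edges(n, p)
  lines <- c("format-version: 1.2")
  for (id in d$ids) {
    e <- d$edges[d$edges$child == id, , drop = FALSE]
    lines <- c(lines, term_stanza(
      id, is_a = e$parent[e$relation == "is_a"],
      part_of = e$parent[e$relation == "part_of"]))
  }
  parse_obo(lines)
}

# Brute-force transitive closure by boolean matrix powers; rows = child,
# cols = reachable ancestor.
closure_matrix <- function(ids, edges) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) A[cbind(edges$child, edges$parent)] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(R, term) sort(colnames(R)[R[term, ]])
oracle_descendants <- function(R, term) sort(rownames(R)[R[, term]])

# Exhaustive hypergeometric tail by enumerating every possible foreground
# draw of size n from N background genes of which K are annotated.
oracle_hyper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K are the annotated ones
  mean(hits >= k)
}

# ---- small expression fixtures ----

fixed_sample <- function(abund, id = "S1", condition = NULL, ...) {
  new_sample(id, abund, condition = condition, ...)
}

# A one-condition, one-sample world: graph with a single annotated node.
single_condition_graph <- function(axes, cond) {
  ann <- data.frame(
    experiment_id = "E", library_id = "L", species_id = cond$species,
    anat_id = cond$anat, cell_type_id = cond$cell_type,
    stage_id = cond$stage, sex = cond$sex, strain = cond$strain,
    free_text_label = "", data_type = "bulk", integrated = TRUE,
    stringsAsFactors = FALSE
  )
  build_condition_graph(axes, ann)
}
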