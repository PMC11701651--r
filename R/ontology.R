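# Ontology handling: OBO parsing, DAG traversal, taxon-constraint filtering.
#
# Only the structural subset of OBO needed for condition annotation is
# honored: [Term] stanzas with id, name, is_a, relationship: part_of and
# is_obsolete. Everything else (logical definitions, other relationship
# types, [Typedef] stanzas) is silently ignored.

OE_RELATIONS <- c("is_a", "part_of")

.new_ontology <- function(ids, term_names, edges) {
  if (anyDuplicated(ids)) {
    oe_error("oe_malformed_stanza",
             sprintf("duplicate term id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  edges <- edges[, c("child", "parent", "relation"), drop = FALSE]
  edges <- unique(edges)
  dangling <- setdiff(unique(c(edges$parent, edges$child)), ids)
  if (length(dangling)) {
    oe_error("oe_dangling_parent",
             sprintf("edge references missing term(s): %s",
                     paste(sort(dangling), collapse = ", ")))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")],
      vertices = data.frame(name = ids), directed = TRUE
    )
    if (!igraph::is_dag(g)) {
      oe_error("oe_cycle", "ontology relations contain a cycle")
    }
  }
  up <- lapply(OE_RELATIONS, function(r) {
    e <- edges[edges$relation == r, , drop = FALSE]
    split(e$parent, factor(e$child, levels = unique(e$child)))
  })
  names(up) <- OE_RELATIONS
  down <- lapply(OE_RELATIONS, function(r) {
    e <- edges[edges$relation == r, , drop = FALSE]
    split(e$child, factor(e$parent, levels = unique(e$parent)))
  })
  names(down) <- OE_RELATIONS
  names(term_names) <- ids
  roots <- sort(setdiff(ids, unique(edges$child)))
  structure(
    list(ids = ids, names = term_names, edges = edges,
         up = up, down = down, roots = roots, cache = new.env(parent = emptyenv())),
    class = "ontology"
  )
}

#' Parse an OBO-format ontology
#'
#' Reads the structural subset of OBO 1.2 used for annotation ontologies:
#' `[Term]` stanzas with `id`, `name`, `is_a`, `relationship: part_of` and
#' `is_obsolete` tags. All other tags and stanza types are ignored. Obsolete
#' terms are dropped together with their outgoing edges; an edge pointing to
#' a missing (or obsolete) term is an error, as is any cycle over the
#' combined `is_a`/`part_of` edge set.
#'
#' @param x Path to an OBO file, a single string containing OBO text, or a
#'   character vector of lines.
#' @return An object of class `"ontology"`: term ids, names, a typed edge
#'   table and root set.
#' @examples
#' onto <- parse_obo(c("[Term]", "id: A:1", "name: root",
#'                     "[Term]", "id: A:2", "name: leaf", "is_a: A:1"))
#' onto$roots
#' @export
parse_obo <- function(x) {
  lines <- trimws(.as_lines(x))
  starts <- grep("^\\[", lines)
  if (!length(starts)) {
    oe_error("oe_malformed_stanza", "no stanzas found in OBO input")
  }
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); obsolete <- logical(0)
  edges <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[seq(starts[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- sub("\\s*!.*$", "", trimws(sub("^[^:]+:", "", body)))
    id <- val[tag == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      oe_error("oe_malformed_stanza",
               sprintf("[Term] stanza at line %d has no id", starts[i]))
    }
    ids <- c(ids, id)
    nm <- val[tag == "name"][1]
    nms <- c(nms, if (is.na(nm)) id else nm)
    obs <- any(tag == "is_obsolete" & tolower(val) == "true")
    obsolete <- c(obsolete, obs)
    if (obs) next
    for (p in val[tag == "is_a"]) {
      edges[[length(edges) + 1L]] <- c(id, sub("\\s.*$", "", p), "is_a")
    }
    rel <- val[tag == "relationship"]
    for (r in rel) {
      parts <- strsplit(r, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        edges[[length(edges) + 1L]] <- c(id, parts[2L], "part_of")
      }
    }
  }
  keep <- !obsolete
  edf <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE) |>
      stats::setNames(c("child", "parent", "relation"))
  } else {
    data.frame(child = character(0), parent = character(0),
               relation = character(0))
  }
  .new_ontology(ids[keep], nms[keep], edf)
}

.check_term <- function(onto, term) {
  if (!term %in% onto$ids) {
    oe_error("oe_unknown_term", sprintf("term '%s' not in ontology", term))
  }
}

.reach <- function(adj, term, relations) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- unlist(lapply(relations, function(r) {
      unlist(adj[[r]][frontier], use.names = FALSE)
    }), use.names = FALSE)
    nxt <- setdiff(unique(nxt), c(seen, term))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

.reach_cached <- function(onto, slot, term, relations) {
  key <- paste(slot, term, paste(sort(relations), collapse = "+"), sep = "\r")
  hit <- onto$cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .reach(onto[[slot]], term, relations)
  assign(key, res, envir = onto$cache)
  res
}

#' Transitive ancestors of a term
#'
#' @param onto An `"ontology"` object.
#' @param term Term CURIE.
#' @param relations Relations to traverse, a subset of
#'   `c("is_a", "part_of")`.
#' @return Sorted character vector of ancestor ids, excluding `term` itself.
#' @export
ancestors <- function(onto, term, relations = OE_RELATIONS) {
  stopifnot(inherits(onto, "ontology"), all(relations %in% OE_RELATIONS))
  .check_term(onto, term)
  .reach_cached(onto, "up", term, relations)
}

#' Transitive descendants of a term
#'
#' Mirror of [ancestors()]: reachability over inverted edges.
#' @inheritParams ancestors
#' @return Sorted character vector of descendant ids, excluding `term`.
#' @export
descendants <- function(onto, term, relations = OE_RELATIONS) {
  stopifnot(inherits(onto, "ontology"), all(relations %in% OE_RELATIONS))
  .check_term(onto, term)
  .reach_cached(onto, "down", term, relations)
}

# Direct parents of a term after transitive reduction: a parent edge is
# redundant when the parent is also an ancestor of another direct parent.
.reduced_parents <- function(onto, term, relations = OE_RELATIONS) {
  ps <- unique(unlist(lapply(relations, function(r) onto$up[[r]][[term]]),
                      use.names = FALSE))
  if (length(ps) <= 1L) return(ps)
  keep <- vapply(ps, function(p) {
    others <- setdiff(ps, p)
    !any(vapply(others, function(q) p %in% ancestors(onto, q, relations),
                logical(1)))
  }, logical(1))
  ps[keep]
}

#' Read a taxon-constraints table
#'
#' Expected TSV columns: `term_id`, `species_id`, `exists` (0/1).
#' @param path File path.
#' @return A `"taxon_constraints"` data frame.
#' @export
read_taxon_constraints <- function(path) {
  tc <- utils::read.delim(path, colClasses = c("character", "character", "integer"))
  .check_columns(tc, c("term_id", "species_id", "exists"), "taxon constraints")
  taxon_constraints(tc$term_id, tc$species_id, tc$exists != 0L)
}

#' Construct a taxon-constraints table
#'
#' Per-species existence flags for ontology terms of a multispecies
#' ontology. In strict mode (the default downstream) a pair absent from the
#' table counts as non-existent.
#'
#' @param term_id,species_id,exists Parallel vectors.
#' @return A `"taxon_constraints"` data frame.
#' @export
taxon_constraints <- function(term_id, species_id, exists) {
  structure(
    data.frame(term_id = as.character(term_id),
               species_id = as.character(species_id),
               exists = as.logical(exists)),
    class = c("taxon_constraints", "data.frame")
  )
}

#' Does a term exist for a species under taxon constraints?
#'
#' @param tc A `"taxon_constraints"` table, or `NULL` (no constraints: every
#'   term exists everywhere).
#' @param term,species Term CURIE and species id.
#' @param permissive If `FALSE` (strict, default) a pair not listed in the
#'   table counts as non-existent; if `TRUE`, as existent.
#' @return Logical scalar.
#' @export
tc_exists <- function(tc, term, species, permissive = FALSE) {
  if (is.null(tc)) return(TRUE)
  hit <- tc$exists[tc$term_id == term & tc$species_id == as.character(species)]
  if (!length(hit)) return(permissive)
  any(hit)
}

#' Restrict an ontology to the terms existing in one species
#'
#' Terms failing the taxon constraints are removed; each parent edge whose
#' target was removed is re-wired to every nearest retained ancestor of the
#' removed parent, preserving reachability among retained terms.
#'
#' @inheritParams tc_exists
#' @param onto An `"ontology"`.
#' @return A new `"ontology"` containing only the retained terms.
#' @export
filter_by_taxon <- function(onto, species, tc, permissive = FALSE) {
  stopifnot(inherits(onto, "ontology"))
  keep <- onto$ids[vapply(onto$ids, tc_exists, logical(1),
                          tc = tc, species = species, permissive = permissive)]
  if (!length(keep)) {
    oe_error("oe_empty_ontology",
             sprintf("no ontology term exists for species '%s'", species))
  }
  keep_set <- new.env(parent = emptyenv(), size = length(keep))
  for (kk in keep) assign(kk, TRUE, envir = keep_set)
  memo <- new.env(parent = emptyenv())
  all_parents <- function(t) {
    unique(unlist(lapply(OE_RELATIONS, function(r) onto$up[[r]][[t]]),
                  use.names = FALSE))
  }
  nearest_retained <- function(t) {
    if (isTRUE(keep_set[[t]])) return(t)
    hit <- memo[[t]]
    if (!is.null(hit)) return(hit)
    res <- sort(unique(unlist(lapply(all_parents(t), nearest_retained),
                              use.names = FALSE)))
    assign(t, res, envir = memo)
    res
  }
  e <- onto$edges[onto$edges$child %in% keep, , drop = FALSE]
  new_edges <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    tgt <- nearest_retained(e$parent[i])
    if (!length(tgt)) return(NULL)
    data.frame(child = e$child[i], parent = tgt, relation = e$relation[i])
  }))
  if (is.null(new_edges)) {
    new_edges <- data.frame(child = character(0), parent = character(0),
                            relation = character(0))
  }
  .new_ontology(keep, unname(onto$names[keep]), new_edges)
}

#' Read a flat controlled vocabulary
#'
#' Two-column TSV `member<TAB>root`; every member's sole parent is the root
#' of the vocabulary (e.g. "any sex" for sex, "wild type" for strain).
#' @param path File path.
#' @return A `"vocabulary"` object.
#' @export
read_vocabulary <- function(path) {
  v <- utils::read.delim(path, colClasses = "character")
  .check_columns(v, c("member", "root"), "vocabulary")
  roots <- unique(v$root)
  if (length(roots) != 1L) {
    oe_error("oe_schema_mismatch",
             sprintf("vocabulary must have a single root, found: %s",
                     paste(roots, collapse = ", ")))
  }
  vocabulary(roots, setdiff(unique(v$member), roots))
}

#' Construct a controlled vocabulary
#' @param root Root label (also a valid value).
#' @param members Member labels, all direct children of the root.
#' @return A `"vocabulary"` object.
#' @export
vocabulary <- function(root, members) {
  structure(list(root = root, members = sort(setdiff(members, root))),
            class = "vocabulary")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d edges, roots: %s\n",
              length(x$ids), nrow(x$edges),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> root '%s', %d members\n",
              x$root, length(x$members)))
  invisible(x)
}
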