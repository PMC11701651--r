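# Post-composed annotation conditions and the condition graph.
#
# A condition is a tuple over five axes: anatomical entity, cell type,
# developmental stage, sex and strain (plus the species id). Anatomy and
# cell type are kept as two separate fields (post-composition): the pair is
# the intersection of a cell type and of an anatomical structure, never a
# fused pre-composed term. Conditions are partially ordered axis-wise by
# ontology ancestry, which yields the condition graph along which
# expression data are propagated and reconciled.

OE_AXES <- c("anat", "cell_type", "stage", "sex", "strain")

#' Bundle the per-axis ontologies and vocabularies of a species
#'
#' @param anatomy `"ontology"` for the anatomy axis.
#' @param stage `"ontology"` for the developmental-stage axis.
#' @param sex,strain `"vocabulary"` objects (roots default to "any sex" and
#'   "wild type").
#' @param cell_type `"ontology"` for the cell-type axis; defaults to
#'   `anatomy` (a composite ontology merging anatomy and cell terms).
#' @param anat_root,cell_root,stage_root Axis root sentinels meaning "any
#'   value". Default to the single root of the respective ontology; the
#'   cell root may be a sentinel not present in the ontology.
#' @param relations Ontology relations traversed for anatomy and cell type.
#' @param stage_relations Relations traversed for stages (exposed
#'   separately because stage ontologies may be navigated over `is_a` only).
#' @return A `"condition_axes"` object.
#' @export
condition_axes <- function(anatomy, stage, sex, strain,
                           cell_type = anatomy,
                           anat_root = NULL, cell_root = NULL,
                           stage_root = NULL,
                           relations = OE_RELATIONS,
                           stage_relations = relations) {
  stopifnot(inherits(anatomy, "ontology"), inherits(stage, "ontology"),
            inherits(sex, "vocabulary"), inherits(strain, "vocabulary"),
            inherits(cell_type, "ontology"))
  pick_root <- function(given, onto, axis) {
    if (!is.null(given)) return(given)
    if (length(onto$roots) != 1L) {
      oe_error("oe_schema_mismatch",
               sprintf("%s ontology has %d roots; supply an explicit %s_root",
                       axis, length(onto$roots), axis))
    }
    onto$roots
  }
  structure(
    list(
      ont = list(anat = anatomy, cell_type = cell_type, stage = stage),
      vocab = list(sex = sex, strain = strain),
      roots = list(
        anat = pick_root(anat_root, anatomy, "anat"),
        cell_type = cell_root %||%
          (if ("CL:0000000" %in% cell_type$ids) "CL:0000000"
           else pick_root(NULL, cell_type, "cell")),
        stage = pick_root(stage_root, stage, "stage"),
        sex = sex$root, strain = strain$root
      ),
      relations = relations, stage_relations = stage_relations
    ),
    class = "condition_axes"
  )
}

.axis_relations <- function(axes, axis) {
  if (axis == "stage") axes$stage_relations else axes$relations
}

.axis_has_term <- function(axes, axis, term) {
  if (axis %in% c("sex", "strain")) {
    v <- axes$vocab[[axis]]
    term == v$root || term %in% v$members
  } else {
    term == axes$roots[[axis]] || term %in% axes$ont[[axis]]$ids
  }
}

#' Compose and validate a condition
#'
#' Builds a post-composed condition from the five annotation axes. `NULL`
#' on any axis means the axis root sentinel. Ontology terms must exist in
#' the respective ontology and, when a taxon-constraints table is given,
#' must exist for the species.
#'
#' @param axes A `"condition_axes"` object.
#' @param anat,cell_type,stage Term CURIEs or `NULL` for the axis root.
#' @param sex,strain Vocabulary labels or `NULL` for the vocabulary root.
#' @param species Species id.
#' @param tc Optional `"taxon_constraints"` table.
#' @param permissive Passed to [tc_exists()].
#' @return A `"condition"` object.
#' @export
compose_condition <- function(axes, anat = NULL, cell_type = NULL,
                              stage = NULL, sex = NULL, strain = NULL,
                              species, tc = NULL, permissive = FALSE) {
  stopifnot(inherits(axes, "condition_axes"))
  vals <- list(anat = anat %||% axes$roots$anat,
               cell_type = cell_type %||% axes$roots$cell_type,
               stage = stage %||% axes$roots$stage,
               sex = sex %||% axes$roots$sex,
               strain = strain %||% axes$roots$strain)
  for (axis in OE_AXES) {
    if (!.axis_has_term(axes, axis, vals[[axis]])) {
      oe_error("oe_unknown_term",
               sprintf("'%s' is not a valid %s value", vals[[axis]], axis))
    }
  }
  if (!is.null(tc)) {
    for (axis in c("anat", "cell_type", "stage")) {
      v <- vals[[axis]]
      if (v %in% axes$ont[[axis]]$ids &&
          !tc_exists(tc, v, species, permissive)) {
        oe_error("oe_term_not_in_species",
                 sprintf("term '%s' does not exist for species '%s'",
                         v, species))
      }
    }
  }
  structure(c(vals, list(species = as.character(species))),
            class = "condition")
}

#' Canonical string key of a condition
#' @param cond A `"condition"` (or a data frame of axis columns).
#' @return Character key(s), axes joined with `"|"`.
#' @export
condition_key <- function(cond) {
  if (inherits(cond, "condition")) {
    return(paste(cond$anat, cond$cell_type, cond$stage, cond$sex,
                 cond$strain, cond$species, sep = "|"))
  }
  paste(cond$anat, cond$cell_type, cond$stage, cond$sex, cond$strain,
        cond$species, sep = "|")
}

#' Collapse a condition onto a subset of axes
#'
#' Axes not selected are replaced by their root sentinel; the operation is
#' idempotent. This implements querying calls for any combination of the
#' condition parameters.
#'
#' @param axes A `"condition_axes"`.
#' @param cond A `"condition"`.
#' @param keep Non-empty subset of `c("anat","cell_type","stage","sex","strain")`.
#' @return A `"condition"`.
#' @export
collapse_condition <- function(axes, cond, keep) {
  stopifnot(length(keep) >= 1L, all(keep %in% OE_AXES))
  out <- cond
  for (axis in setdiff(OE_AXES, keep)) out[[axis]] <- axes$roots[[axis]]
  out
}

# Strict ancestor values per axis (excluding the value itself), with the
# axis root sentinel always reachable.
.axis_anc <- function(axes, axis, value, tc = NULL, species = NULL,
                      permissive = FALSE) {
  root <- axes$roots[[axis]]
  if (value == root) return(character(0))
  if (axis %in% c("sex", "strain")) return(root)
  onto <- axes$ont[[axis]]
  anc <- if (value %in% onto$ids) {
    ancestors(onto, value, .axis_relations(axes, axis))
  } else character(0)
  anc <- sort(unique(c(anc, root)))
  if (!is.null(tc)) {
    anc <- anc[vapply(anc, function(t) {
      !(t %in% onto$ids) || tc_exists(tc, t, species, permissive)
    }, logical(1))]
  }
  anc
}

.axis_anc_sets <- function(axes, cond, tc = NULL) {
  stats::setNames(lapply(OE_AXES, function(axis) {
    .axis_anc(axes, axis, cond[[axis]], tc, cond$species)
  }), OE_AXES)
}

#' All ancestor conditions of a condition
#'
#' The Cartesian product of each axis' `{self} U ancestors`, minus the
#' condition itself. Annotations propagate to every one of these, which is
#' how data annotated to, say, a glial subtype of a brain substructure
#' become retrievable for "glial cells in adult brain".
#'
#' @inheritParams collapse_condition
#' @param tc Optional taxon constraints restricting ancestor terms.
#' @param max_n Guard against combinatorial explosion: error if the
#'   ancestor count would exceed this.
#' @return List of `"condition"` objects.
#' @export
condition_ancestors <- function(axes, cond, tc = NULL, max_n = 1e6) {
  anc <- .axis_anc_sets(axes, cond, tc)
  n <- prod(vapply(anc, length, integer(1)) + 1) - 1
  if (n > max_n) {
    oe_error("oe_condition_explosion",
             sprintf("condition has %g ancestors (cap %g)", n, max_n))
  }
  grid <- expand.grid(
    anat = c(cond$anat, anc$anat), cell_type = c(cond$cell_type, anc$cell_type),
    stage = c(cond$stage, anc$stage), sex = c(cond$sex, anc$sex),
    strain = c(cond$strain, anc$strain),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[-1L, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    structure(c(as.list(grid[i, ]), list(species = cond$species)),
              class = "condition")
  })
}

# Axis-wise ancestor-or-equal product order: TRUE iff `a` is an ancestor of
# (or equal to) `c` on every axis. This is the reachability contract of the
# condition graph, checked independently of the stored edges.
#' Is one condition an ancestor-or-equal of another?
#' @param axes A `"condition_axes"`.
#' @param a,cond `"condition"` objects of the same species.
#' @return Logical scalar (`TRUE` also when `a` equals `cond`).
#' @export
is_condition_ancestor <- function(axes, a, cond) {
  if (!identical(a$species, cond$species)) return(FALSE)
  all(vapply(OE_AXES, function(axis) {
    a[[axis]] == cond[[axis]] ||
      a[[axis]] %in% .axis_anc(axes, axis, cond[[axis]])
  }, logical(1)))
}

# Direct (cover) parent values of an axis value, used for the transitive
# reduction stored as graph edges. In a product of partial orders a cover
# changes exactly one axis by one cover step of that axis.
.axis_cover_parents <- function(axes, axis, value) {
  root <- axes$roots[[axis]]
  if (value == root) return(character(0))
  if (axis %in% c("sex", "strain")) return(root)
  onto <- axes$ont[[axis]]
  if (!value %in% onto$ids) return(character(0))
  cp <- .reduced_parents(onto, value, .axis_relations(axes, axis))
  if (!length(cp)) cp <- root
  cp
}

#' Build the condition graph from a set of annotations
#'
#' Nodes are the annotated conditions plus every inferred ancestor
#' condition; stored edges are the transitive reduction of the axis-wise
#' product order. Reachability (which conditions receive data from which)
#' is answered through the per-annotation ancestor index, not through the
#' edge list.
#'
#' @param axes A `"condition_axes"`.
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param tc Optional taxon constraints.
#' @param max_nodes Hard cap on the inferred node count; exceeded counts
#'   raise an error rather than exhausting memory.
#' @return A `"condition_graph"`: `nodes` (data frame with a `key` column),
#'   `annotated` keys, `edges` (parent/child keys), `anc_of_annotated`
#'   (named list: annotated key -> keys of its ancestors-or-self).
#' @export
build_condition_graph <- function(axes, annotations, tc = NULL,
                                  max_nodes = 1e6) {
  ann <- .annotation_conditions(axes, annotations)
  species <- unique(vapply(ann, function(c) c$species, ""))
  if (length(species) != 1L) {
    oe_error("oe_schema_mismatch",
             "condition graph requires a single species per build")
  }
  keys <- vapply(ann, condition_key, "")
  uniq <- !duplicated(keys)
  ann <- ann[uniq]; keys <- keys[uniq]

  anc_of_annotated <- vector("list", length(ann))
  names(anc_of_annotated) <- keys
  node_rows <- list()
  total <- 0
  for (i in seq_along(ann)) {
    anc <- .axis_anc_sets(axes, ann[[i]], tc)
    n_i <- prod(vapply(anc, length, integer(1)) + 1)
    total <- total + n_i
    if (total > max_nodes) {
      oe_error("oe_condition_explosion",
               sprintf("condition graph exceeds the %g-node cap", max_nodes))
    }
    grid <- expand.grid(
      anat = c(ann[[i]]$anat, anc$anat),
      cell_type = c(ann[[i]]$cell_type, anc$cell_type),
      stage = c(ann[[i]]$stage, anc$stage),
      sex = c(ann[[i]]$sex, anc$sex),
      strain = c(ann[[i]]$strain, anc$strain),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$species <- species
    grid$key <- condition_key(grid)
    anc_of_annotated[[i]] <- grid$key
    node_rows[[i]] <- grid
  }
  nodes <- do.call(rbind, node_rows)
  nodes <- nodes[!duplicated(nodes$key), , drop = FALSE]
  rownames(nodes) <- NULL

  key_set <- new.env(parent = emptyenv(), size = nrow(nodes))
  for (k in nodes$key) assign(k, TRUE, envir = key_set)

  cover_cache <- new.env(parent = emptyenv())
  covers <- function(axis, value) {
    ck <- paste(axis, value, sep = "\r")
    hit <- cover_cache[[ck]]
    if (!is.null(hit)) return(hit)
    res <- .axis_cover_parents(axes, axis, value)
    assign(ck, res, envir = cover_cache)
    res
  }
  eparent <- character(0); echild <- character(0)
  for (i in seq_len(nrow(nodes))) {
    for (axis in OE_AXES) {
      for (v in covers(axis, nodes[[axis]][i])) {
        p <- nodes[i, , drop = FALSE]
        p[[axis]] <- v
        pk <- condition_key(p)
        if (isTRUE(key_set[[pk]])) {
          eparent <- c(eparent, pk); echild <- c(echild, nodes$key[i])
        }
      }
    }
  }
  structure(
    list(nodes = nodes, annotated = keys,
         edges = data.frame(parent = eparent, child = echild),
         anc_of_annotated = anc_of_annotated,
         axes = axes, species = species),
    class = "condition_graph"
  )
}

#' @export
print.condition_graph <- function(x, ...) {
  cat(sprintf("<condition_graph> %d nodes (%d annotated), %d edges, species %s\n",
              nrow(x$nodes), length(x$annotated), nrow(x$edges), x$species))
  invisible(x)
}

# Invert anc_of_annotated: node key -> annotated keys whose data propagate
# to it (the annotated condition itself included).
.annotated_under <- function(graph) {
  pairs_node <- unlist(graph$anc_of_annotated, use.names = FALSE)
  pairs_ann <- rep(names(graph$anc_of_annotated),
                   lengths(graph$anc_of_annotated))
  split(pairs_ann, factor(pairs_node, levels = unique(pairs_node)))
}

.annotation_conditions <- function(axes, annotations) {
  lapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations[i, ]
    structure(list(anat = r$anat_id, cell_type = r$cell_type_id,
                   stage = r$stage_id, sex = r$sex, strain = r$strain,
                   species = as.character(r$species_id)),
              class = "condition")
  })
}

OE_ANNOTATION_COLS <- c("experiment_id", "library_id", "species_id",
                        "anat_id", "cell_type_id", "stage_id", "sex",
                        "strain", "free_text_label", "data_type",
                        "integrated")

#' Read an annotation table
#'
#' One row per bulk library or per single-cell population (for cell
#' populations, `library_id` is `"<library>#<cluster>"`). The verbatim
#' author label is kept in `free_text_label`: mapping free text to an
#' ontology term can lose precision, so the original wording is always
#' retained alongside the ontology annotation.
#'
#' @param path TSV path with columns `experiment_id, library_id,
#'   species_id, anat_id, cell_type_id, stage_id, sex, strain,
#'   free_text_label, data_type, integrated`.
#' @return Data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character")
  .check_columns(ann, OE_ANNOTATION_COLS, "annotations")
  ann$integrated <- ann$integrated %in% c("TRUE", "true", "1")
  ann
}

#' Query annotations with ontology reasoning
#'
#' Filters an annotation table the way the raw-data search works: a species
#' or an experiment must be selected first; within each term axis several
#' terms act as OR; across axes the filters act as AND. For the ontology
#' axes (anatomy, cell type, stage) `include_children` also matches
#' annotations mapped to any descendant of a selected term. Sex and strain
#' are flat vocabularies with no child expansion.
#'
#' @param annotations Annotation data frame.
#' @param axes A `"condition_axes"` (used for descendant expansion).
#' @param species,experiment At least one must be non-`NULL`.
#' @param anat,cell_type,stage,sex,strain Optional character vectors of
#'   accepted values (OR within each axis).
#' @param include_children Named logical for the ontology axes, e.g.
#'   `c(anat = TRUE, cell_type = TRUE, stage = FALSE)`.
#' @param data_type Optional data-type filter.
#' @param integrated_only If `TRUE`, keep only annotations fully integrated
#'   into downstream tools (as opposed to curated-only releases).
#' @return The matching annotation rows; attribute `"observed"` lists the
#'   per-axis values present in the result, for post-filter display.
#' @export
query_annotations <- function(annotations, axes, species = NULL,
                              experiment = NULL, anat = NULL,
                              cell_type = NULL, stage = NULL, sex = NULL,
                              strain = NULL,
                              include_children = c(anat = FALSE,
                                                   cell_type = FALSE,
                                                   stage = FALSE),
                              data_type = NULL, integrated_only = FALSE) {
  if (is.null(species) && is.null(experiment)) {
    oe_error("oe_no_species_or_experiment",
             "select a species or an experiment first")
  }
  keep <- rep(TRUE, nrow(annotations))
  if (!is.null(species)) {
    keep <- keep & annotations$species_id == as.character(species)
  }
  if (!is.null(experiment)) {
    keep <- keep & annotations$experiment_id %in% experiment
  }
  expand <- function(terms, axis) {
    if (!isTRUE(include_children[[axis]])) return(terms)
    onto <- axes$ont[[axis]]
    unique(c(terms, unlist(lapply(intersect(terms, onto$ids), descendants,
                                  onto = onto,
                                  relations = .axis_relations(axes, axis)),
                           use.names = FALSE)))
  }
  if (!is.null(anat)) {
    keep <- keep & annotations$anat_id %in% expand(anat, "anat")
  }
  if (!is.null(cell_type)) {
    keep <- keep & annotations$cell_type_id %in% expand(cell_type, "cell_type")
  }
  if (!is.null(stage)) {
    keep <- keep & annotations$stage_id %in% expand(stage, "stage")
  }
  if (!is.null(sex)) keep <- keep & annotations$sex %in% sex
  if (!is.null(strain)) keep <- keep & annotations$strain %in% strain
  if (!is.null(data_type)) keep <- keep & annotations$data_type %in% data_type
  if (integrated_only) keep <- keep & annotations$integrated
  out <- annotations[keep, , drop = FALSE]
  attr(out, "observed") <- list(
    anat = sort(unique(out$anat_id)),
    cell_type = sort(unique(out$cell_type_id)),
    stage = sort(unique(out$stage_id)),
    sex = sort(unique(out$sex)),
    strain = sort(unique(out$strain)),
    data_type = sort(unique(out$data_type))
  )
  out
}
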