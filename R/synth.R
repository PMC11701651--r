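# Synthetic dataset bundles with known ground truth.
#
# The generator emulates the data model the pipeline consumes: balanced
# toy ontologies for anatomy, cell type and stage; flat sex/strain
# vocabularies; bulk abundance matrices for genes and intergenic regions;
# and droplet single-cell count matrices with author-style cluster maps.
# The intergenic noise floor is log-normal (sd 1 on the log2 scale,
# median 1); expressed genes and planted dubious regions sit at
# `effect_size` times the reference median. Everything is deterministic
# given the seed; independent components draw from separate seeded
# streams so changing one knob does not shift the others' draws.

#' Configuration of the synthetic-data generator
#'
#' Defaults are the generator's study conditions: 2000 genes, 1000
#' intergenic regions of which 100 planted dubious, 12 bulk libraries
#' spread over 6 annotated bulk conditions (2 replicates each), one
#' droplet library of 200 cells in 4 author-annotated clusters, half the
#' genes expressed somewhere, expressed abundances at 8x the reference
#' median, and log-normal noise with sd 1 on the log2 scale.
#'
#' @param seed Mandatory integer seed.
#' @param n_genes,n_intergenic,n_dubious_intergenic Feature counts.
#' @param n_bulk_samples Bulk libraries, distributed round-robin over the
#'   bulk conditions.
#' @param n_conditions Annotated bulk conditions.
#' @param n_cells,n_clusters,reads_per_cell Droplet single-cell shape
#'   (`n_cells` is per library); `n_clusters = 0` disables single-cell
#'   data.
#' @param n_sc_libraries Number of droplet libraries; all annotate the
#'   same cell populations, so each single-cell condition is replicated
#'   across libraries just as bulk conditions are across libraries.
#' @param expressed_fraction Fraction of genes expressed in at least one
#'   condition.
#' @param effect_size Fold change of expressed genes (and planted dubious
#'   regions) over the reference median.
#' @param noise_sdlog2 SD of the log2-scale noise.
#' @param ontology_depth,ontology_branching Shape of the balanced anatomy
#'   and cell-type trees.
#' @param species Species id stamped on every record.
#' @return A validated `"synth_config"` list.
#' @export
synth_config <- function(seed, n_genes = 2000L, n_intergenic = 1000L,
                         n_dubious_intergenic = 100L,
                         n_bulk_samples = 12L, n_conditions = 6L,
                         n_cells = 200L, n_clusters = 4L,
                         n_sc_libraries = 2L, reads_per_cell = 5000L,
                         expressed_fraction = 0.5, effect_size = 8,
                         noise_sdlog2 = 1,
                         ontology_depth = 2L, ontology_branching = 2L,
                         species = "9999") {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    oe_error("oe_invalid_config", "a seed is mandatory")
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_intergenic = as.integer(n_intergenic),
              n_dubious_intergenic = as.integer(n_dubious_intergenic),
              n_bulk_samples = as.integer(n_bulk_samples),
              n_conditions = as.integer(n_conditions),
              n_cells = as.integer(n_cells),
              n_clusters = as.integer(n_clusters),
              n_sc_libraries = as.integer(n_sc_libraries),
              reads_per_cell = as.integer(reads_per_cell),
              expressed_fraction = expressed_fraction,
              effect_size = effect_size, noise_sdlog2 = noise_sdlog2,
              ontology_depth = as.integer(ontology_depth),
              ontology_branching = as.integer(ontology_branching),
              species = as.character(species))
  ok <- cfg$n_genes >= 10L && cfg$n_intergenic >= 10L &&
    cfg$n_dubious_intergenic >= 0L &&
    cfg$n_dubious_intergenic < cfg$n_intergenic &&
    cfg$n_conditions >= 1L && cfg$n_bulk_samples >= cfg$n_conditions &&
    cfg$expressed_fraction >= 0 && cfg$expressed_fraction <= 1 &&
    cfg$effect_size >= 1 && cfg$noise_sdlog2 > 0 &&
    cfg$ontology_depth >= 1L && cfg$ontology_branching >= 1L &&
    (cfg$n_clusters == 0L ||
       (cfg$n_cells >= cfg$n_clusters && cfg$n_sc_libraries >= 1L))
  if (!ok) oe_error("oe_invalid_config", "invalid synthetic configuration")
  structure(cfg, class = "synth_config")
}

# Balanced b-ary tree ontology with ids "<prefix>:%07d"; node 1 is the
# root, parent of node i is (i - 2) %/% b + 1. Edge relations alternate
# is_a / part_of so both relation types are exercised.
.balanced_tree_ontology <- function(prefix, depth, branching,
                                    relations = c("is_a", "part_of")) {
  b <- branching
  n <- if (b == 1L) depth + 1L else (b^(depth + 1L) - 1L) %/% (b - 1L)
  ids <- sprintf("%s:%07d", prefix, seq_len(n))
  if (n == 1L) {
    return(.new_ontology(ids, ids,
                         data.frame(child = character(0),
                                    parent = character(0),
                                    relation = character(0))))
  }
  child <- ids[2:n]
  parent <- ids[((seq(2L, n) - 2L) %/% b) + 1L]
  rel <- rep_len(relations, n - 1L)
  .new_ontology(ids, ids, data.frame(child = child, parent = parent,
                                     relation = rel))
}

.tree_leaves <- function(onto) {
  sort(setdiff(onto$ids, unique(onto$edges$parent)))
}

#' Generate a synthetic dataset bundle with known ground truth
#'
#' @param cfg A `"synth_config"`.
#' @return A list of `bundle` (a `"dataset_bundle"`) and `truth` (a
#'   `"synth_truth"`: logical gene x condition-key matrix `expressed`,
#'   logical per-region vector `dubious`, and the config).
#' @export
simulate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  species <- cfg$species

  # stream 1: ontologies and condition annotations
  set.seed(cfg$seed)
  anatomy <- .balanced_tree_ontology("SANAT", cfg$ontology_depth,
                                     cfg$ontology_branching)
  cells <- .balanced_tree_ontology("SCELL", cfg$ontology_depth,
                                   cfg$ontology_branching)
  stages <- .balanced_tree_ontology("SSTAGE", cfg$ontology_depth, 1L,
                                    relations = "is_a")
  sex <- vocabulary("any sex", c("female", "male"))
  strain <- vocabulary("wild type", c("strain A", "strain B"))
  axes <- condition_axes(anatomy, stages, sex, strain, cell_type = cells)

  n_sc_cond <- if (cfg$n_clusters > 0L) cfg$n_clusters else 0L
  n_cond <- cfg$n_conditions + n_sc_cond
  anat_pool <- .tree_leaves(anatomy)
  cell_pool <- c(.tree_leaves(cells), axes$roots$cell_type)
  stage_pool <- stages$ids
  conds <- list(); keys <- character(0)
  tries <- 0L
  while (length(conds) < n_cond) {
    tries <- tries + 1L
    if (tries > 50L * n_cond) {
      oe_error("oe_invalid_config",
               "ontology too small for the requested number of distinct conditions")
    }
    cand <- compose_condition(
      axes,
      anat = sample(anat_pool, 1L),
      cell_type = sample(cell_pool, 1L),
      stage = sample(stage_pool, 1L),
      sex = sample(c("any sex", "female", "male"), 1L),
      strain = "wild type",
      species = species
    )
    k <- condition_key(cand)
    if (!k %in% keys) {
      conds[[length(conds) + 1L]] <- cand
      keys <- c(keys, k)
    }
  }
  bulk_conds <- conds[seq_len(cfg$n_conditions)]
  sc_conds <- if (n_sc_cond) conds[cfg$n_conditions + seq_len(n_sc_cond)] else list()

  bulk_libs <- sprintf("BULK%03d", seq_len(cfg$n_bulk_samples))
  bulk_cond_idx <- rep_len(seq_len(cfg$n_conditions), cfg$n_bulk_samples)
  clusters <- if (n_sc_cond) sprintf("c%d", seq_len(cfg$n_clusters)) else character(0)

  ann_row <- function(lib, cond, dtype, label) {
    data.frame(experiment_id = "SYNEXP1", library_id = lib,
               species_id = species, anat_id = cond$anat,
               cell_type_id = cond$cell_type, stage_id = cond$stage,
               sex = cond$sex, strain = cond$strain,
               free_text_label = label, data_type = dtype,
               integrated = TRUE, stringsAsFactors = FALSE)
  }
  sc_libs <- if (n_sc_cond) sprintf("SC%03d", seq_len(cfg$n_sc_libraries)) else character(0)
  ann <- do.call(rbind, c(
    lapply(seq_along(bulk_libs), function(i) {
      ann_row(bulk_libs[i], bulk_conds[[bulk_cond_idx[i]]], "bulk", "")
    }),
    unlist(lapply(sc_libs, function(lib) {
      lapply(seq_along(clusters), function(i) {
        ann_row(paste0(lib, "#", clusters[i]), sc_conds[[i]], "sc_droplet",
                sprintf("author cluster %d cells", i))
      })
    }), recursive = FALSE)
  ))

  genes <- sprintf("G%06d", seq_len(cfg$n_genes))
  regions <- sprintf("IG%06d", seq_len(cfg$n_intergenic))
  dubious <- stats::setNames(
    seq_len(cfg$n_intergenic) <= cfg$n_dubious_intergenic, regions
  )

  # stream 2: ground truth
  set.seed(cfg$seed + 1L)
  n_expr <- round(cfg$expressed_fraction * cfg$n_genes)
  expressed_genes <- genes[seq_len(n_expr)]
  truth <- matrix(FALSE, cfg$n_genes, n_cond, dimnames = list(genes, keys))
  if (n_expr > 0L) {
    draw <- matrix(stats::runif(n_expr * n_cond) < 0.5, n_expr, n_cond)
    none <- rowSums(draw) == 0L
    draw[cbind(which(none), sample.int(n_cond, sum(none), replace = TRUE))] <- TRUE
    truth[expressed_genes, ] <- draw
  }

  lognoise <- function(n) 2^stats::rnorm(n, 0, cfg$noise_sdlog2)

  # stream 3: bulk abundances
  set.seed(cfg$seed + 2L)
  genic <- matrix(0, cfg$n_genes, cfg$n_bulk_samples,
                  dimnames = list(genes, bulk_libs))
  for (j in seq_len(cfg$n_bulk_samples)) {
    mu <- ifelse(truth[, bulk_cond_idx[j]], cfg$effect_size, 1)
    genic[, j] <- mu * lognoise(cfg$n_genes)
  }
  intergenic <- matrix(0, cfg$n_intergenic, cfg$n_bulk_samples,
                       dimnames = list(regions, bulk_libs))
  for (j in seq_len(cfg$n_bulk_samples)) {
    mu <- ifelse(dubious, cfg$effect_size, 1)
    intergenic[, j] <- mu * lognoise(cfg$n_intergenic)
  }

  # stream 4: droplet single cell (counts over genes + intergenic
  # regions; cluster expression profiles are redrawn per library, so
  # libraries are independent replicates of the same cell populations)
  set.seed(cfg$seed + 3L)
  sc <- list()
  if (n_sc_cond > 0L) {
    features <- c(genes, regions)
    cells_per <- diff(round(seq(0, cfg$n_cells, length.out = cfg$n_clusters + 1L)))
    cl_of_cell <- rep(clusters, cells_per)
    for (lib_i in seq_along(sc_libs)) {
      barcodes <- sprintf("%s-BC%05d", sc_libs[lib_i], seq_len(sum(cells_per)))
      counts <- matrix(0L, length(features), length(barcodes),
                       dimnames = list(features, barcodes))
      for (i in seq_along(clusters)) {
        ci <- cfg$n_conditions + i
        mu <- c(ifelse(truth[, ci], cfg$effect_size, 1),
                ifelse(dubious, cfg$effect_size, 1))
        w <- mu * lognoise(length(features))
        cols <- which(cl_of_cell == clusters[i])
        counts[, cols] <- stats::rmultinom(length(cols), cfg$reads_per_cell,
                                           w / sum(w))
      }
      sc[[lib_i]] <- list(
        library_id = sc_libs[lib_i],
        counts = Matrix::Matrix(counts, sparse = TRUE),
        clusters = stats::setNames(cl_of_cell, barcodes)
      )
    }
  }

  tc <- taxon_constraints(
    term_id = c(anatomy$ids, cells$ids, stages$ids),
    species_id = species,
    exists = TRUE
  )
  bundle <- structure(
    list(species = species, axes = axes, tc = tc, annotations = ann,
         bulk = list(genic = genic, intergenic = intergenic), sc = sc,
         config = cfg),
    class = "dataset_bundle"
  )
  truth_obj <- structure(
    list(expressed = truth, dubious = dubious, config = cfg),
    class = "synth_truth"
  )
  list(bundle = bundle, truth = truth_obj)
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle> species %s: %d genes, %d intergenic regions, %d bulk libraries, %d sc libraries, %d annotations\n",
    x$species, nrow(x$bulk$genic), nrow(x$bulk$intergenic),
    ncol(x$bulk$genic), length(x$sc), nrow(x$annotations)))
  invisible(x)
}

# Propagate the per-annotated-condition truth upward: a gene counts as
# truly expressed in a node when it is expressed in any annotated
# condition lying at or below that node.
.propagated_truth <- function(truth, graph, keys) {
  under <- .annotated_under(graph)
  ann_keys <- colnames(truth$expressed)
  out <- matrix(FALSE, nrow(truth$expressed), length(keys),
                dimnames = list(rownames(truth$expressed), keys))
  for (i in seq_along(keys)) {
    below <- intersect(under[[keys[i]]], ann_keys)
    if (length(below)) {
      out[, i] <- rowSums(truth$expressed[, below, drop = FALSE]) > 0L
    }
  }
  out
}

#' Compare calls against the simulator's ground truth
#'
#' Confusion counts of present/absent calls against the (upward
#' propagated) truth, overall and stratified by condition depth in the
#' graph, to expose propagation artifacts.
#'
#' @param calls Calls data frame with `gene_id`, `key`, `state`.
#' @param truth A `"synth_truth"`.
#' @param graph The `"condition_graph"` the calls were computed on.
#' @return List: `confusion` (TP/FP/TN/FN), `sensitivity`, `specificity`,
#'   `false_present_rate`, and `by_depth` (one row per condition depth).
#' @export
evaluate_recovery <- function(calls, truth, graph) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!all(calls$gene_id %in% rownames(truth$expressed))) {
    oe_error("oe_key_mismatch", "calls contain genes unknown to the truth")
  }
  keys <- unique(calls$key)
  if (!all(keys %in% graph$nodes$key)) {
    oe_error("oe_key_mismatch", "calls contain conditions not in the graph")
  }
  tr <- .propagated_truth(truth, graph, keys)
  called_present <- calls$state == "present"
  truly <- tr[cbind(match(calls$gene_id, rownames(tr)),
                    match(calls$key, colnames(tr)))]
  tp <- sum(called_present & truly)
  fp <- sum(called_present & !truly)
  fn <- sum(!called_present & truly)
  tn <- sum(!called_present & !truly)
  rate <- function(a, b) if (a + b == 0L) NA_real_ else a / (a + b)
  node_depth <- .node_depths(graph)
  d <- node_depth[calls$key]
  by_depth <- do.call(rbind, lapply(sort(unique(d)), function(dd) {
    i <- d == dd
    data.frame(depth = dd,
               n = sum(i),
               sensitivity = rate(sum(called_present[i] & truly[i]),
                                  sum(!called_present[i] & truly[i])),
               false_present_rate = rate(sum(called_present[i] & !truly[i]),
                                         sum(!called_present[i] & !truly[i])))
  }))
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = rate(tp, fn),
       specificity = rate(tn, fp),
       false_present_rate = rate(fp, tn),
       by_depth = by_depth)
}

# Depth of a condition node: summed per-axis ancestor counts (0 for the
# species root condition).
.node_depths <- function(graph) {
  axes <- graph$axes
  depth_of <- new.env(parent = emptyenv())
  for (axis in OE_AXES) {
    for (v in unique(graph$nodes[[axis]])) {
      assign(paste(axis, v, sep = "\r"),
             length(.axis_anc(axes, axis, v)), envir = depth_of)
    }
  }
  per_axis <- lapply(OE_AXES, function(axis) {
    vapply(graph$nodes[[axis]], function(v) {
      depth_of[[paste(axis, v, sep = "\r")]]
    }, numeric(1))
  })
  stats::setNames(Reduce(`+`, per_axis), graph$nodes$key)
}
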