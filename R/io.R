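# Readers and writers for every external format touched: OBO ontologies,
# TSV tables (annotations, matrices, taxon constraints, vocabularies,
# calls), MTX triplets with features/barcodes sidecars, and the YAML
# bundle config. All TSVs are UTF-8 and tab-delimited; writers emit
# '#'-prefixed comment headers carrying the tool version and parameters
# so outputs are self-documenting and diffable.

OE_CALLS_COLS <- c("gene_id", "anat", "cell_type", "stage", "sex",
                   "strain", "species", "key", "p_integrated", "state",
                   "quality", "data_types", "n_samples_self",
                   "n_samples_descendant", "mean_normalized_rank", "score")

.version_string <- function() {
  as.character(utils::packageVersion("ontoexpress"))
}

.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) .fmt_num(col)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

# '#' only counts as a comment at the start of a line, so ids containing
# '#' (cell-population ids are "<library>#<cluster>") stay intact.
.read_tsv <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' Write a calls-plus-scores table
#'
#' One row per gene and condition, in a fixed, documented column order,
#' deterministically sorted (gene, then condition key) so files are
#' diffable across runs. Numeric columns are written with 12 significant
#' digits.
#'
#' @param calls The joined calls data frame from [run_pipeline()].
#' @param path Output path.
#' @param params Optional named list echoed into the comment header.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path, params = list()) {
  df <- calls
  names(df)[names(df) == "species"] <- "species"
  for (col in setdiff(OE_CALLS_COLS, names(df))) df[[col]] <- NA
  df <- df[, OE_CALLS_COLS, drop = FALSE]
  df <- df[order(df$gene_id, df$key), , drop = FALSE]
  comments <- c(
    sprintf("ontoexpress calls v%s", .version_string()),
    if (length(params)) {
      sprintf("params: %s",
              paste(names(params), unlist(lapply(params, paste, collapse = "+")),
                    sep = "=", collapse = " "))
    },
    "quality tiers are documented stand-ins (see package vignette)"
  )
  .write_tsv(df, path, comments)
}

#' Read back a calls table
#'
#' Validates the exact column order written by [write_calls()]; files with
#' missing, extra or shuffled columns are rejected.
#'
#' @param path File path.
#' @return Calls data frame.
#' @export
read_calls <- function(path) {
  df <- .read_tsv(path, colClasses = c(
    gene_id = "character", anat = "character", cell_type = "character",
    stage = "character", sex = "character", strain = "character",
    species = "character", key = "character", p_integrated = "numeric",
    state = "character", quality = "character", data_types = "character",
    n_samples_self = "integer", n_samples_descendant = "integer",
    mean_normalized_rank = "numeric", score = "numeric"
  ))
  .check_columns(df, OE_CALLS_COLS, "calls file", exact_order = TRUE)
  df
}

#' Write an enrichment result table
#' @param res Result of [topanat()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(res, path) {
  .write_tsv(res, path, sprintf("ontoexpress topanat v%s", .version_string()))
}

# ---- matrices ----

#' Read an abundance matrix TSV
#'
#' First column = feature id, remaining columns = one sample each.
#' @param path File path.
#' @return Numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- id_col
  .write_tsv(df, path)
}

#' Read a droplet single-cell MTX triplet
#'
#' `matrix.mtx` plus one-column `features.tsv` / `barcodes.tsv` sidecars.
#' @param mtx,features,barcodes File paths.
#' @return Sparse feature x barcode count matrix.
#' @export
read_mtx_triplet <- function(mtx, features, barcodes) {
  m <- Matrix::readMM(mtx)
  f <- readLines(features)
  b <- readLines(barcodes)
  if (nrow(m) != length(f) || ncol(m) != length(b)) {
    oe_error("oe_schema_mismatch",
             sprintf("MTX is %d x %d but features/barcodes list %d / %d entries",
                     nrow(m), ncol(m), length(f), length(b)))
  }
  dimnames(m) <- list(f, b)
  m
}

#' Read a barcode-to-cluster map
#' @param path Two-column TSV `barcode<TAB>cluster_id`.
#' @return Named character vector, barcode -> cluster.
#' @export
read_cluster_map <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  .check_columns(df, c("barcode", "cluster_id"), "cluster map")
  stats::setNames(df$cluster_id, df$barcode)
}

# ---- bundle round trip ----

.write_obo <- function(onto, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in onto$ids) {
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", onto$names[[id]])), con)
    e <- onto$edges[onto$edges$child == id, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[i]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[i]), con)
      }
    }
  }
  invisible(path)
}

#' Write a dataset bundle to a directory
#'
#' Emits the complete on-disk form the loader consumes: OBO ontologies,
#' vocabulary and taxon-constraint TSVs, the annotation table, bulk genic
#' and intergenic matrices, per-library MTX triplets with cluster maps,
#' and a `config.yaml` tying them together.
#'
#' @param bundle A `"dataset_bundle"`.
#' @param dir Output directory (created if needed).
#' @return The config file path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  .write_obo(bundle$axes$ont$anat, p("anatomy.obo"))
  .write_obo(bundle$axes$ont$stage, p("stages.obo"))
  composite <- identical(bundle$axes$ont$cell_type, bundle$axes$ont$anat)
  if (!composite) .write_obo(bundle$axes$ont$cell_type, p("cell_types.obo"))
  for (v in c("sex", "strain")) {
    vv <- bundle$axes$vocab[[v]]
    .write_tsv(data.frame(member = c(vv$root, vv$members), root = vv$root),
               p(paste0(v, ".tsv")))
  }
  .write_tsv(data.frame(term_id = bundle$tc$term_id,
                        species_id = bundle$tc$species_id,
                        exists = as.integer(bundle$tc$exists)),
             p("taxon_constraints.tsv"))
  .write_tsv(bundle$annotations, p("annotations.tsv"))
  .write_matrix_tsv(bundle$bulk$genic, p("bulk_genic.tsv"), "gene_id")
  .write_matrix_tsv(bundle$bulk$intergenic, p("bulk_intergenic.tsv"),
                    "region_id")
  sc_cfg <- list()
  for (sc in bundle$sc) {
    d <- p(sc$library_id)
    dir.create(d, showWarnings = FALSE)
    Matrix::writeMM(methods::as(methods::as(sc$counts, "dMatrix"),
                                "generalMatrix"),
                    file.path(d, "matrix.mtx"))
    writeLines(rownames(sc$counts), file.path(d, "features.tsv"))
    writeLines(colnames(sc$counts), file.path(d, "barcodes.tsv"))
    .write_tsv(data.frame(barcode = names(sc$clusters),
                          cluster_id = unname(sc$clusters)),
               file.path(d, "clusters.tsv"))
    sc_cfg[[length(sc_cfg) + 1L]] <- list(
      library_id = sc$library_id,
      mtx = file.path(sc$library_id, "matrix.mtx"),
      features = file.path(sc$library_id, "features.tsv"),
      barcodes = file.path(sc$library_id, "barcodes.tsv"),
      clusters = file.path(sc$library_id, "clusters.tsv")
    )
  }
  cfg <- list(
    species = bundle$species,
    anatomy = "anatomy.obo",
    cell_types = if (composite) "anatomy.obo" else "cell_types.obo",
    stages = "stages.obo",
    sex = "sex.tsv", strain = "strain.tsv",
    taxon_constraints = "taxon_constraints.tsv",
    annotations = "annotations.tsv",
    bulk_genic = "bulk_genic.tsv",
    bulk_intergenic = "bulk_intergenic.tsv",
    cell_root = bundle$axes$roots$cell_type,
    single_cell = sc_cfg
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}

#' Load and validate a dataset bundle
#'
#' Reads every file referenced by a bundle `config.yaml` and checks
#' referential integrity: annotation terms must resolve in the
#' ontologies/vocabularies, clustered barcodes must exist in their count
#' matrices, species ids must be consistent, and bulk genic/intergenic
#' matrices must share their sample columns. All violations are collected
#' and reported together in a single validation error.
#'
#' @param config_path Path to the bundle's `config.yaml`.
#' @return A `"dataset_bundle"`.
#' @export
load_bundle <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)
  p <- function(rel) file.path(dir, rel)
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)

  anatomy <- parse_obo(p(cfg$anatomy))
  cell_types <- if (identical(cfg$cell_types, cfg$anatomy)) anatomy
                else parse_obo(p(cfg$cell_types))
  stages <- parse_obo(p(cfg$stages))
  sex <- read_vocabulary(p(cfg$sex))
  strain <- read_vocabulary(p(cfg$strain))
  tc <- read_taxon_constraints(p(cfg$taxon_constraints))
  axes <- condition_axes(anatomy, stages, sex, strain,
                         cell_type = cell_types,
                         cell_root = cfg$cell_root %||% NULL)
  ann <- read_annotations(p(cfg$annotations))
  genic <- read_matrix_tsv(p(cfg$bulk_genic))
  intergenic <- read_matrix_tsv(p(cfg$bulk_intergenic))

  species <- as.character(cfg$species)
  bad_sp <- unique(ann$species_id[ann$species_id != species])
  if (length(bad_sp)) {
    note(sprintf("annotations carry species %s but config says %s",
                 paste(bad_sp, collapse = ","), species))
  }
  if (!identical(colnames(genic), colnames(intergenic))) {
    note("bulk genic and intergenic matrices have different sample columns")
  }
  overlap <- intersect(rownames(genic), rownames(intergenic))
  if (length(overlap)) {
    note(sprintf("region ids overlap gene ids (e.g. %s)", overlap[1L]))
  }
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    chk <- list(anat = r$anat_id, cell_type = r$cell_type_id,
                stage = r$stage_id, sex = r$sex, strain = r$strain)
    for (axis in names(chk)) {
      if (!.axis_has_term(axes, axis, chk[[axis]])) {
        note(sprintf("annotation '%s': unknown %s term '%s'",
                     r$library_id, axis, chk[[axis]]))
      }
    }
  }
  bulk_ann <- ann$library_id[ann$data_type == "bulk"]
  for (lib in setdiff(bulk_ann, colnames(genic))) {
    note(sprintf("bulk library '%s' missing from the genic matrix", lib))
  }
  sc <- list()
  for (entry in cfg$single_cell %||% list()) {
    counts <- tryCatch(
      read_mtx_triplet(p(entry$mtx), p(entry$features), p(entry$barcodes)),
      ontoexpress_error = function(e) {
        note(sprintf("library '%s': %s", entry$library_id, conditionMessage(e)))
        NULL
      })
    clusters <- read_cluster_map(p(entry$clusters))
    if (!is.null(counts)) {
      missing <- setdiff(names(clusters), colnames(counts))
      for (b in utils::head(missing, 5L)) {
        note(sprintf("library '%s': clustered barcode '%s' missing from matrix",
                     entry$library_id, b))
      }
      pops <- paste0(entry$library_id, "#", sort(unique(unname(clusters))))
      for (pop in setdiff(pops, ann$library_id)) {
        note(sprintf("cell population '%s' has no annotation row", pop))
      }
      sc[[length(sc) + 1L]] <- list(library_id = entry$library_id,
                                    counts = counts, clusters = clusters)
    }
  }
  if (length(issues)) {
    oe_error("oe_validation",
             paste0("bundle validation failed:\n  ",
                    paste(issues, collapse = "\n  ")),
             data = list(issues = issues))
  }
  structure(
    list(species = species, axes = axes, tc = tc, annotations = ann,
         bulk = list(genic = genic, intergenic = intergenic), sc = sc,
         config = cfg),
    class = "dataset_bundle"
  )
}
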