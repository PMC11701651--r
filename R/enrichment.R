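# Anatomical enrichment: GO-style over-representation of anatomy and
# cell-type terms in a gene list, with genes mapped to terms by present
# expression calls rather than functional annotation. Decorrelation of the
# term DAG uses the elim scheme: significant leaf-ward terms have their
# genes removed from their ancestors before those are tested.

#' Map genes to anatomical/cell-type terms via present calls
#'
#' Each gene with a present call is attached to the call's anatomy and
#' cell-type terms and to all their ontology ancestors, so a term's gene
#' set always contains the gene sets of its descendants.
#'
#' @param calls Calls data frame (rows with `state != "present"` are
#'   ignored) carrying `gene_id`, `anat_id`/`anat` and
#'   `cell_type_id`/`cell_type` columns.
#' @param anatomy `"ontology"` for the anatomy terms.
#' @param cell_type `"ontology"` for the cell-type terms (defaults to
#'   `anatomy`, the composite case).
#' @param relations Relations traversed for propagation.
#' @return A `"term_gene_map"`: named list, term -> character vector of
#'   gene ids.
#' @export
map_genes_to_terms <- function(calls, anatomy, cell_type = anatomy,
                               relations = OE_RELATIONS) {
  pick <- function(...) {
    nm <- intersect(c(...), names(calls))
    if (!length(nm)) oe_error("oe_schema_mismatch", "calls lack condition axis columns")
    calls[[nm[1L]]]
  }
  present <- calls$state == "present"
  genes <- calls$gene_id[present]
  anat <- pick("anat_id", "anat")[present]
  cell <- pick("cell_type_id", "cell_type")[present]
  pairs <- unique(data.frame(
    gene = c(genes, genes), term = c(anat, cell), stringsAsFactors = FALSE
  ))
  expand_term <- function(t, onto) {
    if (!t %in% onto$ids) return(character(0))
    c(t, ancestors(onto, t, relations))
  }
  terms <- unique(pairs$term)
  exp_map <- stats::setNames(lapply(terms, function(t) {
    unique(c(expand_term(t, anatomy),
             if (!identical(cell_type, anatomy)) expand_term(t, cell_type)))
  }), terms)
  up <- exp_map[pairs$term]
  long_gene <- rep(pairs$gene, lengths(up))
  long_term <- unlist(up, use.names = FALSE)
  if (!length(long_term)) {
    return(structure(list(), class = "term_gene_map"))
  }
  m <- lapply(split(long_gene, long_term), function(g) sort(unique(g)))
  structure(m[order(names(m))], class = "term_gene_map")
}

#' Upper-tail hypergeometric test
#'
#' Exact probability of observing at least `k` annotated genes in a
#' foreground of size `n` drawn from a background of `N` genes of which
#' `K` are annotated to the term.
#'
#' @param k Foreground genes at the term.
#' @param n Foreground size.
#' @param K Background genes at the term.
#' @param N Background size.
#' @return `P(X >= k)`.
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(k < 0 | k > pmin(n, K) | n > N | K > N)) {
    oe_error("oe_invalid_counts",
             "need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Longest-path depth of each term from the roots (leaves-upward processing
# order for elim).
.term_depths <- function(onto, relations = OE_RELATIONS) {
  memo <- new.env(parent = emptyenv())
  depth <- function(t) {
    hit <- memo[[t]]
    if (!is.null(hit)) return(hit)
    ps <- unique(unlist(lapply(relations, function(r) onto$up[[r]][[t]]),
                        use.names = FALSE))
    d <- if (!length(ps)) 0L else 1L + max(vapply(ps, depth, integer(1)))
    assign(t, d, envir = memo)
    d
  }
  stats::setNames(vapply(onto$ids, depth, integer(1)), onto$ids)
}

#' Anatomical enrichment of a gene list
#'
#' Tests each anatomy/cell-type term for over-representation of the
#' foreground genes among the genes expressed at the term, against a
#' background universe. `method = "classic"` tests every term
#' independently; `method = "elim"` walks the ontology leaves-upward and
#' removes the genes of any term significant at `elim_threshold` from all
#' its ancestors before they are tested, so nested terms do not echo the
#' same signal. P-values are BH-adjusted over the tested terms.
#'
#' @param foreground Character vector of gene ids.
#' @param background Character vector; defaults to every gene present in
#'   `term_map` (the genes with at least one present call). A genome-wide
#'   universe can be supplied instead when a gene universe file is
#'   available.
#' @param term_map A `"term_gene_map"`.
#' @param ontology The `"ontology"` the terms belong to (composite
#'   anatomy + cell type).
#' @param method `"elim"` (default) or `"classic"`.
#' @param elim_threshold Elimination significance cutoff (applied to the
#'   raw p, before FDR).
#' @param min_background Terms with fewer background genes than this are
#'   untestable and skipped (count reported in attribute `"n_skipped"`).
#' @param strict If `TRUE`, foreground genes outside the background raise
#'   an error; otherwise they are dropped with a warning.
#' @return Data frame sorted by p (ties by term id): `term`, `name`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr`, `method`.
#' @export
topanat <- function(foreground, background = NULL, term_map, ontology,
                    method = c("elim", "classic"), elim_threshold = 0.01,
                    min_background = 2L, strict = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(term_map, "term_gene_map"))
  if (!length(foreground)) {
    oe_error("oe_empty_foreground", "foreground gene list is empty")
  }
  background <- background %||%
    sort(unique(unlist(term_map, use.names = FALSE)))
  outside <- setdiff(foreground, background)
  if (length(outside)) {
    if (strict) {
      oe_error("oe_foreground_not_in_background",
               sprintf("%d foreground gene(s) not in background", length(outside)))
    }
    warning(sprintf("dropping %d foreground gene(s) not in background",
                    length(outside)))
    foreground <- intersect(foreground, background)
    if (!length(foreground)) {
      oe_error("oe_empty_foreground",
               "no foreground gene left after background restriction")
    }
  }
  fg <- unique(foreground); bg <- unique(background)
  n <- length(fg); N <- length(bg)
  term_genes <- lapply(term_map, intersect, y = bg)
  K_all <- lengths(term_genes)
  testable <- names(term_genes)[K_all >= min_background]
  n_skipped <- sum(K_all < min_background)
  depths <- .term_depths(ontology)
  ord <- testable[order(-depths[testable], testable)]
  elim <- new.env(parent = emptyenv())
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    t <- ord[i]
    g <- setdiff(term_genes[[t]], elim[[t]] %||% character(0))
    k <- length(intersect(g, fg)); K <- length(g)
    p <- if (K == 0L) 1 else hypergeom_test(k, n, K, N)
    rows[[i]] <- data.frame(term = t, k = k, K = K, n = n, N = N, p = p,
                            stringsAsFactors = FALSE)
    if (method == "elim" && p <= elim_threshold) {
      for (a in ancestors(ontology, t)) {
        assign(a, union(elim[[a]] %||% character(0), term_genes[[t]]),
               envir = elim)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0))
  }
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$method <- method
  res$name <- unname(ontology$names[res$term])
  res <- res[order(res$p, res$term),
             c("term", "name", "k", "K", "n", "N", "p", "fdr", "method")]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}
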