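# Nonparametric 0-100 expression scores.
#
# Pipeline: (1) rank genes within each sample by decreasing abundance
# (fractional ranks, ties averaged); (2) normalize ranks to a common scale
# so protocols measuring different numbers of genes become comparable;
# (3) integrate all normalized ranks of a gene over a condition and its
# graph descendants by an unweighted mean; (4) invert and renormalize so
# the top expressed gene of a condition scores 100.

#' Rank the detectable genes of a sample
#'
#' Fractional (mean-of-ties) ranks by decreasing abundance, over the
#' sample's detectable genes only; rank 1 is the most expressed gene.
#' `max_rank` is the number of detectable expression positions, i.e. the
#' detectable-gene count.
#'
#' @param sample An `"oe_sample"` with at least one detectable gene.
#' @return A `"ranked_sample"`: `sample_id`, named `rank` vector,
#'   `max_rank`.
#' @export
rank_sample <- function(sample) {
  stopifnot(inherits(sample, "oe_sample"))
  g <- sample$detectable_genes
  if (!length(g)) {
    oe_error("oe_empty_sample",
             sprintf("sample '%s' has no detectable gene", sample$sample_id))
  }
  a <- sample$abundance[g]
  r <- rank(-a, ties.method = "average")
  structure(list(sample_id = sample$sample_id, rank = r,
                 max_rank = length(g)),
            class = "ranked_sample")
}

#' Normalize a rank across protocols
#'
#' Rescales a within-sample rank to a common scale: not every protocol can
#' determine every gene's expression level (polyA capture vs
#' ribo-depletion, droplet vs full length), so samples have different
#' numbers of rankable genes. The rank is stretched proportionally:
#' `r * global_max / sample_max`.
#'
#' @param r Fractional rank(s), `1 <= r <= sample_max`.
#' @param sample_max Detectable-gene count of the sample.
#' @param global_max Largest `sample_max` over all samples of the species.
#' @return Normalized rank(s).
#' @export
normalize_rank <- function(r, sample_max, global_max) {
  if (any(r < 1 | r > sample_max) || sample_max > global_max) {
    oe_error("oe_out_of_range",
             "need 1 <= r <= sample_max <= global_max")
  }
  r * global_max / sample_max
}

#' Mean normalized rank of a gene in a condition
#'
#' Unweighted mean of the gene's normalized ranks over every sample
#' annotated to the condition or to any of its graph descendants.
#'
#' @inheritParams call_expression
#' @return List with `mean_normalized_rank`, `condition_max_rank` (the
#'   common normalized scale), and `n_samples`.
#' @export
integrate_rank <- function(gene, condition, graph, samples) {
  key <- if (inherits(condition, "condition")) condition_key(condition) else condition
  under <- .annotated_under(graph)[[key]]
  if (is.null(under)) {
    oe_error("oe_no_data", sprintf("no annotated data under condition '%s'", key))
  }
  skeys <- vapply(samples, function(s) condition_key(s$condition), "")
  global_max <- max(vapply(samples, function(s) length(s$detectable_genes),
                           integer(1)))
  contrib <- samples[skeys %in% under]
  contrib <- Filter(function(s) gene %in% s$detectable_genes, contrib)
  if (!length(contrib)) {
    oe_error("oe_no_data",
             sprintf("gene '%s' is not detectable under condition '%s'",
                     gene, key))
  }
  nr <- vapply(contrib, function(s) {
    rs <- rank_sample(s)
    normalize_rank(unname(rs$rank[gene]), rs$max_rank, global_max)
  }, numeric(1))
  list(mean_normalized_rank = mean(nr), condition_max_rank = global_max,
       n_samples = length(contrib))
}

#' Invert and renormalize a mean rank into a 0-100 score
#'
#' `score = 100 * (M + 1 - mean_rank) / M` where `M` is the condition's
#' max rank: strictly decreasing in the mean rank, equal to 100 for the
#' top-ranked gene and approaching (but never reaching) 0 for the
#' bottom-ranked gene of a large condition.
#'
#' @param mean_rank Mean normalized rank, in `[1, condition_max_rank]`.
#' @param condition_max_rank Rank scale of the condition.
#' @return Score in (0, 100].
#' @export
expression_score <- function(mean_rank, condition_max_rank) {
  if (any(mean_rank < 1 | mean_rank > condition_max_rank)) {
    oe_error("oe_out_of_range",
             "mean_rank must lie in [1, condition_max_rank]")
  }
  100 * (condition_max_rank + 1 - mean_rank) / condition_max_rank
}

#' Expression pattern of a gene, ordered by score
#'
#' Returns the conditions where the gene has a present call, ordered by
#' decreasing expression score (ties broken by condition key), so the
#' domains with the highest expression levels come first. Results can be
#' restricted to data types (e.g. single-cell only); the contributing
#' data types of each call are kept so source data can be traced.
#'
#' @param gene Gene id.
#' @param calls A calls-plus-scores data frame as produced by
#'   [run_pipeline()] (or read back by [read_calls()]).
#' @param data_type Optional character vector: keep only calls supported
#'   by at least one of these data types.
#' @return Data frame of present calls, sorted by score descending.
#' @export
gene_expression_pattern <- function(gene, calls, data_type = NULL) {
  if (!gene %in% calls$gene_id) {
    oe_error("oe_unknown_gene", sprintf("gene '%s' has no call", gene))
  }
  out <- calls[calls$gene_id == gene & calls$state == "present", ,
               drop = FALSE]
  if (!is.null(data_type)) {
    hit <- vapply(strsplit(out$data_types, ",", fixed = TRUE),
                  function(d) any(d %in% data_type), logical(1))
    out <- out[hit, , drop = FALSE]
  }
  out <- out[order(-out$score, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
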