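# Present/absent expression calls.
#
# A gene's expression state in a sample is tested against the empirical
# null distribution of intergenic-region abundances measured in that same
# sample: regions with no annotated gene define the background noise
# level. Per-sample p-values are then integrated per gene over a condition
# and all its graph descendants, yielding one p-value per gene and
# condition; significant means a 'present' call, otherwise 'absent'.

#' Construct a sample
#'
#' One bulk library or one pseudo-bulked cell population, with
#' library-normalized per-feature abundances (TPM/CPM-like). The abundance
#' map covers genes and intergenic regions alike; `detectable_genes` lists
#' the genes the protocol can in principle measure (e.g. polyA selection
#' misses non-polyadenylated transcripts), which bounds both calling and
#' ranking.
#'
#' @param sample_id Unique sample id.
#' @param abundance Named non-negative numeric vector, feature -> abundance.
#' @param detectable_genes Subset of `names(abundance)`; defaults to all.
#' @param condition A `"condition"` the sample is annotated to (optional
#'   for the low-level operations, required by the pipeline).
#' @param data_type One of `"bulk"`, `"sc_droplet"`, `"sc_full_length"`.
#' @param origin `"bulk"` or `"pseudo_bulk"`.
#' @param raw_counts Optional named integer vector of raw counts (kept for
#'   pseudo-bulk samples so count conservation can be audited).
#' @param library_id Originating library (defaults to `sample_id`).
#' @return An `"oe_sample"` object.
#' @export
new_sample <- function(sample_id, abundance,
                       detectable_genes = names(abundance),
                       condition = NULL, data_type = "bulk",
                       origin = c("bulk", "pseudo_bulk"),
                       raw_counts = NULL, library_id = sample_id) {
  origin <- match.arg(origin)
  if (is.null(names(abundance)) || anyNA(abundance) ||
      any(!is.finite(abundance)) || any(abundance < 0)) {
    oe_error("oe_invalid_abundance",
             sprintf("sample '%s': abundances must be named, finite and >= 0",
                     sample_id))
  }
  if (!all(detectable_genes %in% names(abundance))) {
    oe_error("oe_invalid_abundance",
             sprintf("sample '%s': detectable genes missing from abundance map",
                     sample_id))
  }
  structure(
    list(sample_id = sample_id, abundance = abundance,
         detectable_genes = detectable_genes, condition = condition,
         data_type = data_type, origin = origin, raw_counts = raw_counts,
         library_id = library_id),
    class = "oe_sample"
  )
}

#' @export
print.oe_sample <- function(x, ...) {
  cat(sprintf("<sample '%s'> %s/%s, %d features, %d detectable genes\n",
              x$sample_id, x$data_type, x$origin, length(x$abundance),
              length(x$detectable_genes)))
  invisible(x)
}

#' Select the stringent reference set of intergenic regions
#'
#' Bulk data are used to spot dubious intergenic regions -- regions whose
#' expression level suggests an unannotated gene -- and exclude them from
#' the background null. The default rule is a robust outlier screen on the
#' regions themselves: a region is discarded when its mean
#' log2(abundance + 1) across bulk samples exceeds the median of the
#' region means by more than `k` median absolute deviations. Clean noise
#' regions are retained essentially in full (keeping the null calibrated),
#' while regions expressed at gene-like levels stand many MADs above the
#' noise floor and are discarded. A `"genic_quantile"` rule is also
#' offered: discard regions whose mean exceeds the `q`-th percentile of
#' the protein-coding gene means (appropriate when virtually all genes in
#' the genic table are expressed).
#'
#' @param intergenic Numeric matrix, regions x bulk samples, with region
#'   ids as rownames.
#' @param genic Numeric matrix, genes x the same bulk samples; required
#'   for the `"genic_quantile"` rule.
#' @param rule `"mad"` (default) or `"genic_quantile"`.
#' @param k MAD multiplier for the `"mad"` rule.
#' @param q Percentile (0-100) for the `"genic_quantile"` rule.
#' @return Character vector of retained region ids.
#' @export
select_reference_intergenic <- function(intergenic, genic = NULL,
                                        rule = c("mad", "genic_quantile"),
                                        k = 4, q = 5) {
  rule <- match.arg(rule)
  intergenic <- as.matrix(intergenic)
  if (nrow(intergenic) < 10L) {
    oe_error("oe_too_few_regions",
             sprintf("need >= 10 intergenic regions, got %d", nrow(intergenic)))
  }
  if (is.null(rownames(intergenic))) {
    oe_error("oe_schema_mismatch", "intergenic matrix must have region ids as rownames")
  }
  m <- rowMeans(log2(intergenic + 1))
  if (rule == "mad") {
    thr <- stats::median(m) + k * stats::mad(m)
  } else {
    if (is.null(genic)) {
      oe_error("oe_schema_mismatch", "genic matrix required for rule 'genic_quantile'")
    }
    gm <- rowMeans(log2(as.matrix(genic) + 1))
    thr <- stats::quantile(gm, q / 100, names = FALSE)
  }
  keep <- rownames(intergenic)[m <= thr]
  if (!length(keep)) {
    oe_error("oe_all_regions_dubious", "every intergenic region was discarded")
  }
  keep
}

# Vectorized empirical right-tail p-values for many genes in one sample.
# k = number of reference regions with abundance >= the gene's abundance
# (ties count toward k: conservative), p = (k + 1) / (n + 1).
.sample_pvalues <- function(sample, genes, reference) {
  ref <- sample$abundance[reference[reference %in% names(sample$abundance)]]
  n <- length(ref)
  if (n < 10L) {
    oe_error("oe_empty_reference",
             sprintf("sample '%s': %d reference regions present, need >= 10",
                     sample$sample_id, n))
  }
  sref <- sort(unname(ref))
  g <- sample$abundance[genes]
  below <- findInterval(g, sref, left.open = TRUE)  # regions strictly < gene
  (n - below + 1) / (n + 1)
}

#' Empirical p-value of a gene against the intergenic null
#'
#' Right-tail empirical p-value of the gene's abundance within the
#' distribution of the reference intergenic regions of the same sample,
#' with add-one correction: `p = (k + 1) / (n + 1)` where `k` counts
#' reference regions at or above the gene (ties counted, conservative).
#' Guarantees `p` in (0, 1], monotone non-increasing in abundance, and a
#' super-uniform null.
#'
#' @param sample An `"oe_sample"`.
#' @param gene Gene id; must be detectable in the sample.
#' @param reference Character vector of reference region ids (>= 10 must
#'   be measured in the sample).
#' @return A `"gene_pvalue"`: list with `gene`, `sample_id`, `p`.
#' @export
present_pvalue <- function(sample, gene, reference) {
  stopifnot(inherits(sample, "oe_sample"))
  if (!gene %in% sample$detectable_genes) {
    oe_error("oe_gene_not_detectable",
             sprintf("gene '%s' is not detectable in sample '%s'",
                     gene, sample$sample_id))
  }
  p <- unname(.sample_pvalues(sample, gene, reference))
  structure(list(gene = gene, sample_id = sample$sample_id, p = p),
            class = "gene_pvalue")
}

#' Pseudo-bulk a droplet single-cell count matrix
#'
#' Aggregates the raw reads of all cells belonging to a same population
#' within one library into one bulk-like sample per population. Cell
#' populations are the authors' original clusters -- the data are never
#' re-clustered here. Unassigned barcodes are ignored (their count is
#' reported in a message); per-gene raw counts over assigned barcodes are
#' conserved exactly across the resulting samples.
#'
#' @param counts Feature x barcode count matrix (dense or `Matrix` sparse)
#'   with dimnames.
#' @param barcode_to_cluster Named character vector: barcode -> cluster id.
#' @param cluster_conditions Optional named list: cluster id ->
#'   `"condition"` attached to the resulting sample.
#' @param library_id Library the cells come from; sample ids are
#'   `"<library_id>#<cluster>"`.
#' @param data_type Data type recorded on the samples.
#' @param strict If `TRUE` (default), a clustered barcode absent from the
#'   matrix is an error; otherwise it is dropped with a warning.
#' @return Named list of `"oe_sample"` objects (abundances CPM-normalized
#'   over all features; raw summed counts kept in `$raw_counts`).
#' @export
pseudobulk <- function(counts, barcode_to_cluster, cluster_conditions = NULL,
                       library_id = "library", data_type = "sc_droplet",
                       strict = TRUE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    oe_error("oe_schema_mismatch", "count matrix must carry feature and barcode dimnames")
  }
  bc <- names(barcode_to_cluster)
  missing <- setdiff(bc, colnames(counts))
  if (length(missing)) {
    if (strict) {
      oe_error("oe_unknown_barcode",
               sprintf("%d clustered barcode(s) missing from the matrix, e.g. %s",
                       length(missing), missing[1L]))
    }
    warning(sprintf("dropping %d clustered barcode(s) missing from the matrix",
                    length(missing)))
    barcode_to_cluster <- barcode_to_cluster[!bc %in% missing]
    bc <- names(barcode_to_cluster)
  }
  unassigned <- setdiff(colnames(counts), bc)
  if (length(unassigned)) {
    message(sprintf("pseudobulk: %d unassigned barcode(s) ignored",
                    length(unassigned)))
  }
  clusters <- sort(unique(unname(barcode_to_cluster)))
  out <- lapply(clusters, function(cl) {
    cells <- bc[barcode_to_cluster == cl]
    if (!length(cells)) {
      oe_error("oe_empty_cluster", sprintf("cluster '%s' has no cells", cl))
    }
    raw <- if (length(cells) == 1L) {
      as.numeric(counts[, cells])
    } else {
      as.numeric(Matrix::rowSums(counts[, cells, drop = FALSE]))
    }
    names(raw) <- rownames(counts)
    tot <- sum(raw)
    ab <- if (tot > 0) raw / tot * 1e6 else raw
    new_sample(
      sample_id = paste0(library_id, "#", cl),
      abundance = ab,
      condition = cluster_conditions[[cl]],
      data_type = data_type, origin = "pseudo_bulk",
      raw_counts = raw, library_id = library_id
    )
  })
  stats::setNames(out, vapply(out, function(s) s$sample_id, ""))
}

#' Combine per-sample p-values
#'
#' Integrates the p-values a gene collected across all samples of a
#' condition and its child conditions. `"fisher"`: chi-square tail of
#' `-2 * sum(log p)` with `2k` df. `"stouffer"`: normal tail of
#' `sum(z) / sqrt(k)`. `"bh_best"`: the best Benjamini-Hochberg-adjusted
#' p-value, `min_i p_(i) * k / i`, capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method One of `"fisher"`, `"stouffer"`, `"bh_best"`.
#' @return Combined p-value (scalar).
#' @export
combine_pvalues <- function(p, method = c("fisher", "stouffer", "bh_best")) {
  method <- match.arg(method)
  if (!length(p)) oe_error("oe_empty_list", "no p-values to combine")
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    oe_error("oe_out_of_range", "p-values must lie in (0, 1]")
  }
  k <- length(p)
  switch(method,
    fisher = stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE),
    stouffer = stats::pnorm(sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(k),
                            lower.tail = FALSE),
    bh_best = min(1, min(sort(p) * k / seq_len(k)))
  )
}

# Quality tiers (documented stand-ins; the production tiers are not
# published): present calls are gold when >= 2 contributing samples are
# individually significant, silver otherwise. Absent calls with an
# integrated p in (alpha, 2*alpha] are bronze (borderline); other absent
# calls are gold with >= 2 individually non-significant samples, silver
# otherwise.
.call_quality <- function(present, p_int, n_sig, n_nonsig, alpha) {
  ifelse(present,
         ifelse(n_sig >= 2L, "gold", "silver"),
         ifelse(p_int <= 2 * alpha, "bronze",
                ifelse(n_nonsig >= 2L, "gold", "silver")))
}

#' Present/absent call for one gene in one condition
#'
#' Collects the gene's per-sample p-values from every sample annotated to
#' the condition or to any of its graph descendants, combines them, and
#' classifies the gene as present when the integrated p-value is at most
#' `alpha`.
#'
#' @param gene Gene id.
#' @param condition A `"condition"` or its key.
#' @param graph A `"condition_graph"`.
#' @param samples Named list of `"oe_sample"`, each carrying a condition.
#' @param reference Reference intergenic region ids.
#' @param alpha Significance level (default 0.05).
#' @param method Combination method, see [combine_pvalues()].
#' @return An `"expression_call"` with `p_integrated`, `state`, `quality`,
#'   `data_types`, `n_samples_self`, `n_samples_descendant`.
#' @export
call_expression <- function(gene, condition, graph, samples, reference,
                            alpha = 0.05, method = "fisher") {
  key <- if (inherits(condition, "condition")) condition_key(condition) else condition
  under <- .annotated_under(graph)[[key]]
  if (is.null(under)) {
    oe_error("oe_no_data", sprintf("no annotated data under condition '%s'", key))
  }
  skeys <- vapply(samples, function(s) condition_key(s$condition), "")
  contrib <- samples[skeys %in% under]
  contrib <- Filter(function(s) gene %in% s$detectable_genes, contrib)
  if (!length(contrib)) {
    oe_error("oe_no_data",
             sprintf("gene '%s' has no detectable data under condition '%s'",
                     gene, key))
  }
  ps <- vapply(contrib, function(s) unname(.sample_pvalues(s, gene, reference)),
               numeric(1))
  p_int <- combine_pvalues(ps, method)
  present <- p_int <= alpha
  n_self <- sum(vapply(contrib, function(s) condition_key(s$condition) == key,
                       logical(1)))
  structure(
    list(gene = gene, condition_key = key, p_integrated = p_int,
         state = if (present) "present" else "absent",
         quality = .call_quality(present, p_int, sum(ps <= alpha),
                                 sum(ps > alpha), alpha),
         data_types = sort(unique(vapply(contrib, function(s) s$data_type, ""))),
         n_samples_self = n_self,
         n_samples_descendant = length(contrib) - n_self),
    class = "expression_call"
  )
}
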