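# End-to-end integration: per-sample p-values and ranks, propagated over
# the condition graph and integrated into one call and one score per gene
# and condition.
#
# Conditions sharing the same set of contributing samples are processed as
# one group, so the per-gene work is vectorized across the whole gene set
# instead of looping over gene x condition pairs.

.sample_keys <- function(samples) {
  vapply(samples, function(s) {
    if (is.null(s$condition)) {
      oe_error("oe_no_data",
               sprintf("sample '%s' carries no condition annotation",
                       s$sample_id))
    }
    condition_key(s$condition)
  }, "")
}

.target_keys <- function(graph, conditions) {
  if (identical(conditions, "annotated")) return(graph$annotated)
  if (identical(conditions, "all")) return(graph$nodes$key)
  missing <- setdiff(conditions, graph$nodes$key)
  if (length(missing)) {
    oe_error("oe_unknown_term",
             sprintf("condition(s) not in graph: %s",
                     paste(utils::head(missing, 3L), collapse = ", ")))
  }
  conditions
}

# Group target condition keys by the set of samples contributing to them.
.condition_groups <- function(graph, skeys, keys) {
  under <- .annotated_under(graph)
  members <- lapply(keys, function(k) which(skeys %in% under[[k]]))
  sig <- vapply(members, paste, "", collapse = ",")
  idx <- split(seq_along(keys), sig)
  lapply(idx, function(i) list(keys = keys[i], samples = members[[i[1L]]]))
}

# genes x samples matrix of per-sample empirical p-values (NA where the
# gene is not detectable in the sample).
.pvalue_matrix <- function(samples, genes, reference) {
  P <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, names(samples)))
  for (j in seq_along(samples)) {
    det <- intersect(genes, samples[[j]]$detectable_genes)
    if (length(det)) P[det, j] <- .sample_pvalues(samples[[j]], det, reference)
  }
  P
}

.normalized_rank_matrix <- function(samples, genes) {
  global_max <- max(vapply(samples, function(s) length(s$detectable_genes),
                           integer(1)))
  NR <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, names(samples)))
  for (j in seq_along(samples)) {
    rs <- rank_sample(samples[[j]])
    det <- intersect(genes, names(rs$rank))
    NR[det, j] <- normalize_rank(rs$rank[det], rs$max_rank, global_max)
  }
  list(NR = NR, global_max = global_max)
}

.combine_matrix <- function(Psub, method) {
  K <- rowSums(!is.na(Psub))
  if (method == "fisher") {
    stat <- -2 * rowSums(log(Psub), na.rm = TRUE)
    p <- stats::pchisq(stat, df = 2 * K, lower.tail = FALSE)
  } else if (method == "stouffer") {
    z <- stats::qnorm(Psub, lower.tail = FALSE)
    p <- stats::pnorm(rowSums(z, na.rm = TRUE) / sqrt(K), lower.tail = FALSE)
  } else {
    p <- apply(Psub, 1L, function(row) {
      row <- row[!is.na(row)]
      if (!length(row)) return(NA_real_)
      combine_pvalues(row, "bh_best")
    })
  }
  p[K == 0L] <- NA_real_
  list(p = p, K = K)
}

#' Present/absent calls for all genes over the condition graph
#'
#' Vectorized equivalent of [call_expression()] applied to every gene and
#' every target condition: per-sample p-values against the intergenic
#' reference are combined over each condition's contributing samples
#' (those annotated to it or to any graph descendant).
#'
#' @param graph A `"condition_graph"`.
#' @param samples Named list of `"oe_sample"` with conditions.
#' @param reference Reference intergenic region ids.
#' @param genes Gene universe; defaults to the union of detectable genes.
#' @param alpha Significance level.
#' @param method Combination method, see [combine_pvalues()].
#' @param conditions `"annotated"` (default) to emit calls for the
#'   annotated conditions, `"all"` for every graph node, or a character
#'   vector of condition keys.
#' @return Data frame: `gene_id`, `key`, `p_integrated`, `state`,
#'   `quality`, `data_types`, `n_samples_self`, `n_samples_descendant`.
#' @export
compute_calls <- function(graph, samples, reference, genes = NULL,
                          alpha = 0.05, method = "fisher",
                          conditions = "annotated") {
  skeys <- .sample_keys(samples)
  genes <- genes %||%
    sort(unique(unlist(lapply(samples, `[[`, "detectable_genes"),
                       use.names = FALSE)))
  keys <- .target_keys(graph, conditions)
  P <- .pvalue_matrix(samples, genes, reference)
  dtypes <- vapply(samples, function(s) s$data_type, "")
  groups <- .condition_groups(graph, skeys, keys)
  out <- vector("list", length(groups))
  gi <- 0L
  for (grp in groups) {
    S <- grp$samples
    if (!length(S)) next
    cmb <- .combine_matrix(P[, S, drop = FALSE], method)
    keep <- which(cmb$K > 0L)
    if (!length(keep)) next
    p_int <- cmb$p[keep]
    n_sig <- rowSums(P[keep, S, drop = FALSE] <= alpha, na.rm = TRUE)
    n_nonsig <- cmb$K[keep] - n_sig
    present <- p_int <= alpha
    dt <- paste(sort(unique(dtypes[S])), collapse = ",")
    n_self <- vapply(grp$keys, function(k) sum(skeys[S] == k), integer(1))
    ng <- length(keep); nk <- length(grp$keys)
    gi <- gi + 1L
    out[[gi]] <- data.frame(
      gene_id = rep(genes[keep], times = nk),
      key = rep(grp$keys, each = ng),
      p_integrated = rep(p_int, times = nk),
      state = rep(ifelse(present, "present", "absent"), times = nk),
      quality = rep(.call_quality(present, p_int, n_sig, n_nonsig, alpha),
                    times = nk),
      data_types = dt,
      n_samples_self = rep(n_self, each = ng),
      n_samples_descendant = rep(length(S) - n_self, each = ng),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[seq_len(gi)])
  if (is.null(res)) {
    oe_error("oe_no_data", "no condition received any data")
  }
  res[order(res$gene_id, res$key), , drop = FALSE]
}

#' Expression scores for all genes over the condition graph
#'
#' Vectorized rank -> normalize -> integrate -> invert pipeline: the mean
#' normalized rank of each gene over a condition's contributing samples is
#' inverted onto the (0, 100] score scale.
#'
#' @inheritParams compute_calls
#' @return Data frame: `gene_id`, `key`, `mean_normalized_rank`, `score`.
#' @export
compute_scores <- function(graph, samples, genes = NULL,
                           conditions = "annotated") {
  skeys <- .sample_keys(samples)
  genes <- genes %||%
    sort(unique(unlist(lapply(samples, `[[`, "detectable_genes"),
                       use.names = FALSE)))
  keys <- .target_keys(graph, conditions)
  nrm <- .normalized_rank_matrix(samples, genes)
  groups <- .condition_groups(graph, skeys, keys)
  out <- vector("list", length(groups))
  gi <- 0L
  for (grp in groups) {
    S <- grp$samples
    if (!length(S)) next
    sub <- nrm$NR[, S, drop = FALSE]
    K <- rowSums(!is.na(sub))
    keep <- which(K > 0L)
    if (!length(keep)) next
    mean_rank <- rowMeans(sub[keep, , drop = FALSE], na.rm = TRUE)
    cond_max <- nrm$global_max
    sc <- expression_score(mean_rank, cond_max)
    ng <- length(keep); nk <- length(grp$keys)
    gi <- gi + 1L
    out[[gi]] <- data.frame(
      gene_id = rep(genes[keep], times = nk),
      key = rep(grp$keys, each = ng),
      mean_normalized_rank = rep(unname(mean_rank), times = nk),
      score = rep(unname(sc), times = nk),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[seq_len(gi)])
  if (is.null(res)) oe_error("oe_no_data", "no condition received any data")
  res[order(res$gene_id, res$key), , drop = FALSE]
}

#' Run the full integration pipeline on a dataset bundle
#'
#' Materializes samples (pseudo-bulking single-cell libraries), selects
#' the stringent intergenic reference from the bulk data, builds the
#' condition graph from the annotations, computes present/absent calls
#' and expression scores, and joins them into one table per gene and
#' condition.
#'
#' @param bundle A `"dataset_bundle"` (see [load_bundle()] /
#'   [simulate_bundle()]).
#' @param alpha Significance level for present calls.
#' @param method P-value combination method.
#' @param conditions Which conditions to emit (see [compute_calls()]).
#' @param reference_rule,reference_k,reference_q Passed to
#'   [select_reference_intergenic()].
#' @return List: `calls` (joined calls + scores data frame with the five
#'   condition axes spelled out), `graph`, `reference`, `samples`,
#'   `params`.
#' @export
run_pipeline <- function(bundle, alpha = 0.05, method = "fisher",
                         conditions = "annotated",
                         reference_rule = "mad", reference_k = 4,
                         reference_q = 5) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  samples <- bundle_samples(bundle)
  reference <- select_reference_intergenic(
    bundle$bulk$intergenic, bundle$bulk$genic,
    rule = reference_rule, k = reference_k, q = reference_q
  )
  graph <- build_condition_graph(bundle$axes, bundle$annotations,
                                 tc = bundle$tc)
  genes <- rownames(bundle$bulk$genic)
  calls <- compute_calls(graph, samples, reference, genes = genes,
                         alpha = alpha, method = method,
                         conditions = conditions)
  scores <- compute_scores(graph, samples, genes = genes,
                           conditions = conditions)
  merged <- merge(calls, scores, by = c("gene_id", "key"), all.x = TRUE,
                  sort = FALSE)
  ax <- graph$nodes[match(merged$key, graph$nodes$key),
                    c("anat", "cell_type", "stage", "sex", "strain",
                      "species")]
  merged <- cbind(merged[, "gene_id", drop = FALSE], ax,
                  merged[, setdiff(names(merged), "gene_id"),
                         drop = FALSE])
  merged <- merged[order(merged$gene_id, merged$key), , drop = FALSE]
  rownames(merged) <- NULL
  list(calls = merged, graph = graph, reference = reference,
       samples = samples,
       params = list(alpha = alpha, method = method,
                     conditions = conditions,
                     reference_rule = reference_rule,
                     reference_k = reference_k, reference_q = reference_q))
}

#' Materialize the samples of a dataset bundle
#'
#' Bulk libraries become one sample each (genic and intergenic abundances
#' merged into one feature map); each single-cell library is pseudo-bulked
#' into one sample per annotated cell population.
#'
#' @param bundle A `"dataset_bundle"`.
#' @return Named list of `"oe_sample"`.
#' @export
bundle_samples <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  ann <- bundle$annotations
  conds <- .annotation_conditions(bundle$axes, ann)
  names(conds) <- ann$library_id
  genes <- rownames(bundle$bulk$genic)
  out <- list()
  bulk_ann <- ann[ann$data_type == "bulk", , drop = FALSE]
  for (i in seq_len(nrow(bulk_ann))) {
    lib <- bulk_ann$library_id[i]
    ab <- c(bundle$bulk$genic[, lib], bundle$bulk$intergenic[, lib])
    out[[lib]] <- new_sample(
      sample_id = lib, abundance = ab, detectable_genes = genes,
      condition = conds[[lib]], data_type = "bulk", origin = "bulk"
    )
  }
  for (sc in bundle$sc) {
    cl <- sort(unique(unname(sc$clusters)))
    cc <- stats::setNames(
      conds[paste0(sc$library_id, "#", cl)], cl
    )
    dt <- ann$data_type[match(paste0(sc$library_id, "#", cl[1L]),
                              ann$library_id)]
    ps <- pseudobulk(sc$counts, sc$clusters, cluster_conditions = cc,
                     library_id = sc$library_id,
                     data_type = if (is.na(dt)) "sc_droplet" else dt)
    for (s in ps) {
      s$detectable_genes <- intersect(names(s$abundance), genes)
      out[[s$sample_id]] <- s
    }
  }
  out
}
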