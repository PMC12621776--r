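#' Spearman correlation matrix between samples
#'
#' Pairwise Spearman correlation of expression profiles, the similarity
#' used everywhere samples are ranked by expression: choosing feature
#' samples for model training, choosing the reference models to
#' ensemble, and the k-nearest-neighbour baseline. Tied expression
#' values receive average ranks.
#'
#' @param expr An [expression_table()] (the log2 stage is recommended;
#'   Spearman is invariant to the monotone transform itself but the
#'   recommendation keeps stages consistent across the pipeline) or a
#'   genes-by-samples numeric matrix.
#' @return Symmetric samples-by-samples correlation matrix with unit
#'   diagonal.
#' @export
spearman_matrix <- function(expr) {
  values <- if (inherits(expr, "ExpressionTable")) expr$values else as.matrix(expr)
  if (nrow(values) < 2) stopf("need at least 2 genes")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance expression in sample(s): %s",
          paste(colnames(values)[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(values, method = "spearman")
  diag(cm) <- 1
  cm
}

#' Rank a sample's nearest neighbours by expression similarity
#'
#' Returns the `k` samples most correlated with the query, in
#' descending correlation order, excluding the query itself. Exact ties
#' preserve the samples' input (column) order.
#'
#' @param query_id Sample id of the query (a row/column of
#'   `corr_matrix`).
#' @param corr_matrix Correlation matrix from [spearman_matrix()],
#'   possibly sliced to the eligible candidate set.
#' @param k Number of neighbours, `1 <= k <= ncol(corr_matrix) - 1`.
#' @param candidates Optional sample ids eligible as neighbours
#'   (default all except the query).
#' @return A list of class `NeighborRanking` with fields `query_id`,
#'   `neighbor_ids` and `correlations`.
#' @export
rank_neighbors <- function(query_id, corr_matrix, k, candidates = NULL) {
  ids <- colnames(corr_matrix)
  if (!query_id %in% rownames(corr_matrix)) stopf("unknown query sample '%s'", query_id)
  if (is.null(candidates)) candidates <- ids
  candidates <- setdiff(candidates, query_id)
  if (!is_count(k) || k < 1 || k > length(candidates)) {
    stopf("k must be in [1, %d]", length(candidates))
  }
  # keep input column order among candidates so ties resolve stably
  candidates <- ids[ids %in% candidates]
  corr <- corr_matrix[query_id, candidates]
  ord <- order(-corr)  # stable: ties keep candidate order
  top <- ord[seq_len(k)]
  structure(list(query_id = query_id, neighbor_ids = candidates[top],
                 correlations = unname(corr[top])),
            class = "NeighborRanking")
}
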