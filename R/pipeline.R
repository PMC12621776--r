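#' Impute chromatin states for query samples
#'
#' End-to-end convenience wrapper around the full pipeline: joint
#' expression preprocessing (quantile normalization + log2), Spearman
#' ranking, per-reference multinomial lasso training for the references
#' each query needs, ensemble prediction and hard assignment.
#'
#' @param queries An [expression_table()] (stage `raw_tpm`) holding the
#'   query samples' expression over the same gene set as the reference
#'   compendium, or a named numeric vector for a single query.
#' @param reference A list with elements `expression` (an
#'   [expression_table()], stage `raw_tpm`) and `annotations` (named
#'   list of [state_annotation()]s), e.g. a [generate_compendium()]
#'   result restricted to the training samples.
#' @param L Feature samples per model.
#' @param R Ensemble size (models averaged per query).
#' @param lambda Lasso penalty.
#' @param n_positions Training positions per model.
#' @param seed Base seed for position subsampling.
#' @param positions Bin indices to predict at (default all bins).
#' @param models Optional pre-trained model list (from
#'   [train_reference_models()]); missing models for needed references
#'   are trained on the fly.
#' @return Named list, one element per query, each with `soft`
#'   ([soft_annotation()]), `hard` ([state_annotation()]) and
#'   `references` (the ensembled reference ids).
#' @export
impute_states <- function(queries, reference, L = 5, R = 3, lambda = 1e-4,
                          n_positions = 3000, seed = 1, positions = NULL,
                          models = list()) {
  ref_expr <- reference$expression
  annotations <- reference$annotations
  stopifnot(inherits(ref_expr, "ExpressionTable"))
  if (is.numeric(queries) && is.null(dim(queries))) {
    queries <- expression_table(matrix(queries, ncol = 1,
                                       dimnames = list(names(queries), "query")),
                                "raw_tpm")
  }
  if (!identical(rownames(queries$values), rownames(ref_expr$values))) {
    stopf("query and reference gene sets differ")
  }
  reference_ids <- ref_expr$sample_ids
  query_ids <- queries$sample_ids
  if (length(intersect(query_ids, reference_ids)) > 0) {
    stopf("query ids overlap reference ids")
  }
  combined <- expression_table(cbind(ref_expr$values, queries$values), "raw_tpm")
  log_expr <- preprocess_expression(combined)
  corr <- spearman_matrix(log_expr)

  # which references do the queries actually need models for?
  needed <- unique(unlist(lapply(query_ids, function(q) {
    rank_neighbors(q, corr, R, candidates = reference_ids)$neighbor_ids
  })))
  to_train <- setdiff(needed, names(models))
  if (length(to_train) > 0) {
    models <- c(models,
                train_reference_models(corr, annotations,
                                       reference_ids = reference_ids,
                                       train_ids = to_train, L = L,
                                       lambda = lambda,
                                       n_positions = n_positions,
                                       seed = seed))
  }
  out <- lapply(query_ids, function(q) {
    soft <- ensemble_predict(q, corr, models, annotations, R,
                             reference_ids = reference_ids,
                             positions = positions)
    list(soft = soft, hard = hard_assign(soft),
         references = attr(soft, "references"))
  })
  names(out) <- query_ids
  attr(out, "models") <- models
  out
}
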