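#' Filter genes by biotype and chromosome
#'
#' Restricts an expression table to genes annotated with an allowed
#' biotype on an allowed chromosome. The defaults keep protein-coding
#' genes on the autosomes and chromosome X, the standard restriction
#' before cross-sample normalization.
#'
#' @param expr An [expression_table()] at stage `raw_tpm`.
#' @param genes Gene records as returned by [read_gene_annotation()]
#'   (needs columns `gene_id`, `chrom`, `biotype`).
#' @param allowed_biotype Biotypes to keep (default `protein_coding`).
#' @param allowed_chroms Chromosomes to keep (default chr1-chr22, chrX).
#' @return Filtered [expression_table()]; row order follows the input
#'   order of the surviving genes.
#' @export
filter_genes <- function(expr, genes,
                         allowed_biotype = "protein_coding",
                         allowed_chroms = paste0("chr", c(1:22, "X"))) {
  stopifnot(inherits(expr, "ExpressionTable"))
  if (expr$stage != "raw_tpm") stopf("filter_genes expects stage 'raw_tpm', got '%s'", expr$stage)
  ok <- genes$biotype %in% allowed_biotype & genes$chrom %in% allowed_chroms
  keep_ids <- genes$gene_id[ok]
  keep <- expr$gene_ids %in% keep_ids
  if (!any(keep)) stopf("no genes survive the biotype/chromosome filter")
  expression_table(expr$values[keep, , drop = FALSE], expr$stage)
}

#' Quantile normalization across samples
#'
#' Forces every sample's expression values onto a common distribution:
#' the across-sample mean of the sorted value vectors. Ties within a
#' sample receive the mean of the corresponding reference quantiles.
#' Delegates to `limma::normalizeQuantiles` with tie handling enabled.
#'
#' @param expr An [expression_table()] at stage `raw_tpm`.
#' @return An [expression_table()] at stage `quantile_normalized`.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "ExpressionTable"))
  if (expr$stage != "raw_tpm") stopf("quantile_normalize expects stage 'raw_tpm', got '%s'", expr$stage)
  if (ncol(expr$values) < 1) stopf("need at least one sample")
  norm <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(norm) <- dimnames(expr$values)
  expression_table(norm, "quantile_normalized")
}

#' Log2 transform with pseudocount
#'
#' Applies `log2(x + pseudocount)` to normalized expression values; the
#' default pseudocount of 1 maps zeros to zero and leaves rank order
#' (hence Spearman correlations) unchanged.
#'
#' @param expr An [expression_table()] at stage `quantile_normalized`.
#' @param pseudocount Positive value added before the logarithm.
#' @return An [expression_table()] at stage `log2`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionTable"))
  if (expr$stage != "quantile_normalized") {
    stopf("log_transform expects stage 'quantile_normalized', got '%s'", expr$stage)
  }
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  if (any(expr$values + pseudocount <= 0)) stopf("value + pseudocount <= 0")
  expression_table(log2(expr$values + pseudocount), "log2")
}

#' Standard expression preprocessing
#'
#' Convenience wrapper: quantile normalization followed by the
#' log2(x + 1) transform. Gene filtering, when gene records are
#' available, should be applied first with [filter_genes()].
#'
#' @param expr An [expression_table()] at stage `raw_tpm`.
#' @param pseudocount Pseudocount for [log_transform()].
#' @return An [expression_table()] at stage `log2`.
#' @export
preprocess_expression <- function(expr, pseudocount = 1) {
  log_transform(quantile_normalize(expr), pseudocount)
}
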