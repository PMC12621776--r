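# Comparison methods: majority state, expression-KNN, and the
# closest-reference benchmark.

# bins x S count matrix of state occurrences across annotations;
# missing bins contribute nothing.
state_counts <- function(anns) {
  S <- length(anns[[1]]$alphabet)
  n <- length(anns[[1]]$states)
  counts <- matrix(0L, n, S)
  for (a in anns) {
    s <- a$states
    ok <- which(!is.na(s))
    idx <- cbind(ok, s[ok])
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# Modal state per bin with seeded uniform tie-breaking; the tie RNG is
# consumed bin-by-bin in bin order. All-zero rows give NA.
modal_state <- function(counts, seed = NULL) {
  first <- max.col(counts, ties.method = "first")
  last <- max.col(counts, ties.method = "last")
  states <- first
  tie <- which(first != last)
  if (length(tie) > 0) {
    states[tie] <- with_seed(seed, vapply(tie, function(i) {
      cand <- which(counts[i, ] == counts[i, first[i]])
      cand[sample.int(length(cand), 1L)]
    }, integer(1)))
  }
  states[rowSums(counts) == 0L] <- NA_integer_
  states
}

#' Majority-state baseline
#'
#' Assigns each position the state most frequent across the reference
#' annotations; frequency ties are resolved by a seeded uniform draw
#' among the tied maxima. Also returns the full per-position state
#' frequency matrix, which serves as the baseline's soft assignment.
#'
#' @param anns Named list of reference [state_annotation()]s.
#' @param seed Seed for tie-breaking.
#' @return List with `annotation` (a [state_annotation()], `NA` at
#'   all-missing bins) and `frequencies` (bins x S matrix; rows sum to
#'   1 over non-missing contributors, all-missing rows are `NA`).
#' @export
majority_state <- function(anns, seed = 1) {
  stopifnot(length(anns) >= 1)
  counts <- state_counts(anns)
  states <- modal_state(counts, seed)
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot == 0L, NA_real_, tot)
  list(annotation = state_annotation("majority", states,
                                     anns[[1]]$genome, anns[[1]]$alphabet),
       frequencies = freqs)
}

#' k-nearest-neighbour state prediction
#'
#' Predicts a query's chromatin states as the per-position modal state
#' over its `k` expression-nearest reference samples (Spearman
#' ranking, as in the main method), with seeded tie-breaking. The
#' per-position state frequencies over the `k` neighbours are returned
#' as the soft assignment.
#'
#' @param query_id Query sample id (a column of `corr`).
#' @param corr Correlation matrix covering query and references.
#' @param annotations Named list of reference [state_annotation()]s.
#' @param k Number of neighbours.
#' @param reference_ids Candidate reference ids (default the
#'   annotation names).
#' @param seed Seed for tie-breaking.
#' @return List with `annotation`, `frequencies` (multiples of `1/k`)
#'   and `neighbor_ids`.
#' @export
knn_predict <- function(query_id, corr, annotations, k,
                        reference_ids = names(annotations), seed = 1) {
  nb <- rank_neighbors(query_id, corr, k, candidates = reference_ids)
  counts <- state_counts(annotations[nb$neighbor_ids])
  states <- modal_state(counts, seed)
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot == 0L, NA_real_, tot)
  list(annotation = state_annotation(query_id, states,
                                     annotations[[1]]$genome,
                                     annotations[[1]]$alphabet),
       frequencies = freqs,
       neighbor_ids = nb$neighbor_ids)
}

#' Closest-reference benchmark
#'
#' Finds the reference annotation with the highest pairwise agreement
#' (fraction of co-annotated positions with identical state) with the
#' target. Because it needs the target's true annotation it is an
#' upper-bound benchmark, not an imputation method. Ties go to the
#' first reference in input order.
#'
#' @param target_ann Target [state_annotation()].
#' @param anns Named list of reference [state_annotation()]s.
#' @param positions Optional bin indices to restrict the comparison to.
#' @return List with `reference_id`, `agreement`, and the per-reference
#'   `agreements` vector.
#' @export
closest_reference <- function(target_ann, anns, positions = NULL) {
  agreements <- vapply(anns, function(a) {
    pairwise_agreement(target_ann, a, positions)
  }, numeric(1))
  best <- which.max(agreements)  # first index on ties
  list(reference_id = names(anns)[best], agreement = agreements[[best]],
       agreements = agreements)
}

#' Pairwise agreement between two annotations
#'
#' Fraction of positions (non-missing in both) carrying the same state
#' label. Symmetric in its arguments; identical to prediction accuracy
#' when one argument is a prediction and the other the observation.
#'
#' @param a,b [state_annotation()]s or integer state vectors.
#' @param positions Optional bin indices to restrict to.
#' @return Agreement fraction in [0, 1].
#' @export
pairwise_agreement <- function(a, b, positions = NULL) {
  x <- state_vector(a); y <- state_vector(b)
  if (length(x) != length(y)) stopf("annotations differ in length")
  if (!is.null(positions)) { x <- x[positions]; y <- y[positions] }
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stopf("no common non-missing positions")
  mean(x[ok] == y[ok])
}
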