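#' Prediction accuracy
#'
#' Fraction of positions where the predicted hard state label matches
#' the observed one, over positions non-missing in both.
#'
#' @param pred,obs [state_annotation()]s or integer state vectors.
#' @param positions Optional bin indices to restrict the comparison to.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(pred, obs, positions = NULL) {
  pairwise_agreement(pred, obs, positions)
}

#' Area under the precision-recall curve (stepwise interpolation)
#'
#' Threshold points are the unique score values in decreasing order;
#' at each threshold, items with score >= threshold count as predicted
#' positive. Precision is held constant between consecutive recall
#' points: AUPRC = sum_i (Recall_i - Recall_{i-1}) * Precision_i with
#' Recall_0 = 0. Constant scores therefore give the positive
#' prevalence, perfect separation gives 1.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary ground-truth labels (0/1 or logical); both
#'   classes must be present.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  P <- sum(labels)
  if (P == 0 || P == length(labels)) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  cum_tp <- cumsum(y)
  # last index of each run of equal scores = one threshold point
  idx <- c(which(diff(s) != 0), length(s))
  precision <- cum_tp[idx] / idx
  recall <- cum_tp[idx] / P
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Computed with the exact tie-corrected rank (Mann-Whitney) formula,
#' which equals the area under the ROC curve with linear interpolation
#' between unique score points:
#' P(score_pos > score_neg) + 0.5 * P(score_pos = score_neg).
#'
#' @inheritParams auprc
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  P <- sum(labels)
  N <- length(labels) - P
  if (P == 0 || N == 0) stopf("both classes must be present")
  r <- rank(scores)  # average ranks on ties
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

# Per-state confusion summary between two hard annotations.
per_state_overlap <- function(pred, obs, n_states = NULL) {
  x <- state_vector(pred); y <- state_vector(obs)
  S <- max(n_states_of(pred, n_states), n_states_of(obs, n_states))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  both <- tabulate(x[x == y], nbins = S)
  pred_n <- tabulate(x, nbins = S)
  obs_n <- tabulate(y, nbins = S)
  union <- pred_n + obs_n - both
  precision <- ifelse(pred_n > 0, both / pred_n, NA_real_)
  recall <- ifelse(obs_n > 0, both / obs_n, NA_real_)
  f1 <- ifelse(pred_n + obs_n > 0, 2 * both / (pred_n + obs_n), NA_real_)
  data.frame(state = seq_len(S), pred_n = pred_n, obs_n = obs_n,
             intersection = both, union = union,
             jaccard = ifelse(union > 0, both / union, NA_real_),
             precision = precision, recall = recall, f1 = f1)
}

#' Per-state Jaccard index
#'
#' For each state, the ratio of positions carrying that state in both
#' annotations (intersection) to positions carrying it in either
#' (union). States absent from both are undefined (`NA`) and excluded
#' from weighted averages.
#'
#' @inheritParams accuracy
#' @param n_states Number of states (inferred from annotations when
#'   omitted).
#' @return Numeric vector of per-state Jaccard indices.
#' @export
jaccard_per_state <- function(pred, obs, n_states = NULL) {
  per_state_overlap(pred, obs, n_states)$jaccard
}

#' Per-state F1 score
#'
#' F1 = 2 * precision * recall / (precision + recall), treating each
#' state in turn as the positive class; equivalently
#' 2|intersection| / (|pred| + |obs|). States absent from both
#' annotations are undefined (`NA`).
#'
#' @inheritParams jaccard_per_state
#' @return Numeric vector of per-state F1 scores.
#' @export
f1_per_state <- function(pred, obs, n_states = NULL) {
  per_state_overlap(pred, obs, n_states)$f1
}

#' Size-weighted average over states
#'
#' Weighted mean of per-state values with weights proportional to state
#' sizes. Sizes are conventionally the per-state bin counts averaged
#' over the fully observed reference compendium (see [state_sizes()]).
#' Undefined (`NA`) values are dropped and the weights renormalized.
#'
#' @param values Per-state values (e.g. Jaccard or F1), `NA` allowed.
#' @param sizes Non-negative per-state weights, not all zero.
#' @return The weighted average.
#' @export
weighted_state_average <- function(values, sizes) {
  if (length(values) != length(sizes)) stopf("values and sizes differ in length")
  if (any(sizes < 0)) stopf("negative state size")
  ok <- !is.na(values)
  if (sum(sizes[ok]) == 0) stopf("all usable weights are zero")
  sum(values[ok] * sizes[ok]) / sum(sizes[ok])
}

#' Average state sizes over a reference compendium
#'
#' Per-state bin counts averaged across the reference annotations; the
#' standard weights for [weighted_state_average()].
#'
#' @param anns List of [state_annotation()]s.
#' @param n_states Number of states (default from the first alphabet).
#' @return Numeric vector of average per-state bin counts.
#' @export
state_sizes <- function(anns, n_states = length(anns[[1]]$alphabet)) {
  counts <- vapply(anns, function(a) {
    tabulate(state_vector(a)[!is.na(state_vector(a))], nbins = n_states)
  }, numeric(n_states))
  rowMeans(counts)
}

#' Genome fraction per state
#'
#' For hard annotations, the fraction of (non-missing) positions
#' assigned to each state; for soft annotations, the per-state column
#' sums of the probability matrix over the number of positions. Either
#' way the fractions sum to 1.
#'
#' @param x A [state_annotation()] or [soft_annotation()].
#' @param n_states Number of states (hard input only).
#' @return Named numeric vector of per-state genome fractions.
#' @export
genome_fraction <- function(x, n_states = NULL) {
  if (inherits(x, "SoftAnnotation")) {
    f <- colSums(x$probs) / nrow(x$probs)
    names(f) <- x$alphabet
    return(f)
  }
  s <- state_vector(x)
  S <- n_states_of(x, n_states)
  s <- s[!is.na(s)]
  f <- tabulate(s, nbins = S) / length(s)
  if (inherits(x, "StateAnnotation")) names(f) <- x$alphabet
  f
}
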