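#' Hard chromatin-state annotation
#'
#' A per-bin vector of hard state labels for one sample over a
#' [binned_genome()]. States are stored as integer indices into the
#' state alphabet; `NA` marks bins without an annotation (such bins are
#' dropped from any computation that touches them).
#'
#' @param sample_id Sample identifier.
#' @param states Integer vector of state indices (1..S) with `NA` for
#'   missing bins; length must equal the genome's bin count.
#' @param genome A [binned_genome()].
#' @param alphabet Ordered state names; default the 18-state alphabet
#'   (or `S1..Sn` when `states` exceeds 18 levels).
#' @return An object of class `StateAnnotation`.
#' @export
state_annotation <- function(sample_id, states, genome,
                             alphabet = default_state_alphabet(max(18L, max(states, na.rm = TRUE)))) {
  states <- as.integer(states)
  if (length(states) != genome$n_bins) {
    stopf("states has length %d but genome has %d bins", length(states), genome$n_bins)
  }
  bad <- !is.na(states) & (states < 1L | states > length(alphabet))
  if (any(bad)) stopf("state index out of alphabet range at %d bin(s)", sum(bad))
  structure(list(sample_id = as.character(sample_id), states = states,
                 alphabet = alphabet, genome = genome),
            class = "StateAnnotation")
}

#' @export
print.StateAnnotation <- function(x, ...) {
  cat(sprintf("StateAnnotation '%s': %d bins, %d-state alphabet, %d missing\n",
              x$sample_id, length(x$states), length(x$alphabet),
              sum(is.na(x$states))))
  invisible(x)
}

#' Probabilistic ("soft") chromatin-state annotation
#'
#' A bins-by-states matrix of state probabilities for one sample; every
#' row sums to 1 (within 1e-6). May cover a subset of genome bins, in
#' which case `positions` records the global bin indices of the rows.
#'
#' @param sample_id Sample identifier.
#' @param probs Numeric matrix, rows = positions, columns = states.
#' @param alphabet Ordered state names matching `ncol(probs)`.
#' @param positions Global bin indices of the rows (default 1..nrow).
#' @param genome Optional [binned_genome()] the positions refer to.
#' @return An object of class `SoftAnnotation`.
#' @export
soft_annotation <- function(sample_id, probs,
                            alphabet = default_state_alphabet(ncol(probs)),
                            positions = seq_len(nrow(probs)), genome = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(alphabet)) stopf("probs must have one column per state")
  if (length(positions) != nrow(probs)) stopf("positions must match rows of probs")
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) stopf("probabilities outside [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) {
    stopf("%d probability row(s) do not sum to 1 (max deviation %.2e)",
          sum(abs(rs - 1) > 1e-6), max(abs(rs - 1)))
  }
  colnames(probs) <- alphabet
  structure(list(sample_id = as.character(sample_id), probs = probs,
                 alphabet = alphabet, positions = as.integer(positions),
                 genome = genome),
            class = "SoftAnnotation")
}

#' @export
print.SoftAnnotation <- function(x, ...) {
  cat(sprintf("SoftAnnotation '%s': %d positions x %d states\n",
              x$sample_id, nrow(x$probs), ncol(x$probs)))
  invisible(x)
}

#' Hard state assignment from a soft annotation
#'
#' Assigns each position the state with the highest probability; exact
#' ties go to the lowest state index so the assignment is
#' deterministic.
#'
#' @param soft A [soft_annotation()].
#' @return A [state_annotation()] when the soft annotation carries a
#'   genome (bins outside `soft$positions` are `NA`); otherwise a bare
#'   integer vector of argmax state indices.
#' @export
hard_assign <- function(soft) {
  stopifnot(inherits(soft, "SoftAnnotation"))
  if (any(rowSums(soft$probs) == 0)) stopf("all-zero probability row")
  idx <- max.col(soft$probs, ties.method = "first")
  if (is.null(soft$genome)) return(idx)
  states <- rep(NA_integer_, soft$genome$n_bins)
  states[soft$positions] <- idx
  state_annotation(soft$sample_id, states, soft$genome, soft$alphabet)
}
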