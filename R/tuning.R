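#' Cross-validation fold plan
#'
#' Splits samples into `n_folds` disjoint test sets (each roughly
#' `1/n_folds` of the samples) and, within each fold, splits the
#' remainder into a tuning set (a fraction `tuning_frac`, at least one
#' sample) and a training set. Every sample appears in exactly one test
#' set across folds; the plan is deterministic given `seed`.
#'
#' The same machinery serves production-style single splits: with
#' `n_folds = 1` and `test_frac = 0` the plan degenerates to one
#' training/tuning split (e.g. `tuning_frac = 0.2`).
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_folds Number of folds (default 5).
#' @param tuning_frac Fraction of each fold's non-test samples used for
#'   tuning (default 0.06).
#' @param seed Integer seed.
#' @return A list of class `FoldPlan`; each element has `test`,
#'   `tuning` and `training` id vectors.
#' @export
make_folds <- function(sample_ids, n_folds = 5, tuning_frac = 0.06, seed = 1) {
  n <- length(sample_ids)
  if (n < n_folds) stopf("fewer samples (%d) than folds (%d)", n, n_folds)
  shuffled <- with_seed(seed, sample(sample_ids))
  fold_of <- rep_len(seq_len(n_folds), n)
  plan <- lapply(seq_len(n_folds), function(f) {
    test <- shuffled[fold_of == f]
    rest <- shuffled[fold_of != f]
    n_tune <- max(1L, round(tuning_frac * length(rest)))
    if (n_tune >= length(rest)) stopf("tuning set would swallow the training set")
    list(test = test, tuning = rest[seq_len(n_tune)],
         training = rest[-seq_len(n_tune)])
  })
  structure(plan, class = "FoldPlan", seed = seed)
}

#' Hyperparameter grid
#'
#' The default search grid for the ensemble size `R`, the number of
#' feature samples `L`, and the lasso penalty `lambda`.
#'
#' @param R_values Candidate ensemble sizes.
#' @param L_values Candidate feature-sample counts.
#' @param lambda_values Candidate lasso penalties.
#' @return data.frame of all (R, L, lambda) combinations.
#' @export
hyper_grid <- function(R_values = c(3, 5, 10), L_values = c(5, 10, 15),
                       lambda_values = c(0.1, 0.01, 0.001, 0.0001)) {
  stopifnot(length(R_values) > 0, length(L_values) > 0, length(lambda_values) > 0)
  expand.grid(R = R_values, L = L_values, lambda = lambda_values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Select the lasso penalty by state coverage
#'
#' Small penalties can leave rare states without any hard-assigned
#' position in a sample; the penalty is therefore chosen first, by the
#' state-coverage criterion: for each candidate `lambda`, average over
#' every (R, L, tuning sample) cell the number of states with at least
#' one hard-assigned position, and keep the `lambda` maximizing that
#' average. Exact ties go to the smallest `lambda`.
#'
#' @param results data.frame with columns `lambda`, `R`, `L`, `sample`
#'   and `n_states_assigned` (count of states with >= 1 assigned
#'   position in that tuning sample), one row per grid cell x sample.
#' @param grid Optional [hyper_grid()] used to check completeness.
#' @return The selected `lambda` (scalar), with the per-lambda scores
#'   as attribute `scores`.
#' @export
select_lambda <- function(results, grid = NULL) {
  req <- c("lambda", "R", "L", "sample", "n_states_assigned")
  if (!all(req %in% names(results))) {
    stopf("results must have columns %s", paste(req, collapse = ", "))
  }
  if (!is.null(grid)) {
    have <- unique(results[c("R", "L", "lambda")])
    miss <- !apply(grid, 1, function(g) {
      any(have$R == g["R"] & have$L == g["L"] & have$lambda == g["lambda"])
    })
    if (any(miss)) stopf("missing tuning results for %d grid cell(s)", sum(miss))
  }
  scores <- tapply(results$n_states_assigned, results$lambda, mean)
  lambdas <- as.numeric(names(scores))
  best <- max(scores)
  chosen <- min(lambdas[scores == best])  # tie -> smallest lambda
  structure(chosen, scores = stats::setNames(as.numeric(scores), names(scores)))
}

#' Select ensemble size and feature count by median accuracy
#'
#' With the penalty fixed at `lambda_star`, keeps the (R, L) cell whose
#' median accuracy over the tuning samples is highest. Exact ties go to
#' the smaller `R`, then the smaller `L`.
#'
#' @param results data.frame with columns `lambda`, `R`, `L`, `sample`,
#'   `accuracy`.
#' @param lambda_star The penalty selected by [select_lambda()].
#' @return Named numeric vector `c(R = ..., L = ...)` with the per-cell
#'   median accuracies as attribute `scores`.
#' @export
select_R_L <- function(results, lambda_star) {
  req <- c("lambda", "R", "L", "sample", "accuracy")
  if (!all(req %in% names(results))) {
    stopf("results must have columns %s", paste(req, collapse = ", "))
  }
  sub <- results[results$lambda == lambda_star, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no tuning results at lambda = %g", lambda_star)
  cells <- unique(sub[c("R", "L")])
  cells$median_accuracy <- apply(cells, 1, function(cell) {
    stats::median(sub$accuracy[sub$R == cell["R"] & sub$L == cell["L"]])
  })
  best <- max(cells$median_accuracy)
  top <- cells[cells$median_accuracy == best, , drop = FALSE]
  top <- top[order(top$R, top$L), , drop = FALSE]  # ties -> smaller R, then L
  structure(c(R = top$R[1], L = top$L[1]), scores = cells)
}
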