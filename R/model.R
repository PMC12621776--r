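#' Sample training positions from the genome
#'
#' Draws `n` distinct bin indices uniformly without replacement,
#' reproducibly from `seed`. Models are trained on such a random
#' subsample of positions (100,000 genome-wide in typical full-scale
#' use) rather than on every bin.
#'
#' @param genome A [binned_genome()].
#' @param n Number of positions to draw.
#' @param seed Integer seed.
#' @return Sorted integer vector of `n` global bin indices.
#' @export
sample_positions <- function(genome, n, seed) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (n > genome$n_bins) stopf("n = %d exceeds the genome's %d bins", n, genome$n_bins)
  sort(with_seed(seed, sample.int(genome$n_bins, n)))
}

#' One-hot encode neighbour chromatin states
#'
#' Builds the binary feature matrix for model training/prediction: for
#' each of the `L` feature samples (neighbour slots) a block of `S`
#' columns, with a single 1 per slot marking the neighbour's state at
#' the position. Column order is slot-major, state-minor.
#'
#' @param feature_anns List of `L` [state_annotation()]s, in neighbour
#'   rank order; all must be non-missing at `positions`.
#' @param positions Global bin indices to encode.
#' @return Sparse binary matrix (`length(positions)` x `L*S`).
#' @export
encode_features <- function(feature_anns, positions) {
  stopifnot(length(feature_anns) >= 1)
  S <- length(feature_anns[[1]]$alphabet)
  L <- length(feature_anns)
  n <- length(positions)
  jj <- integer(n * L)
  for (l in seq_len(L)) {
    s <- feature_anns[[l]]$states[positions]
    if (anyNA(s)) {
      stopf("feature sample '%s' is missing at %d requested position(s)",
            feature_anns[[l]]$sample_id, sum(is.na(s)))
    }
    jj[(l - 1L) * n + seq_len(n)] <- (l - 1L) * S + s
  }
  Matrix::sparseMatrix(i = rep.int(seq_len(n), L), j = jj, x = 1,
                       dims = c(n, L * S))
}

#' Train one reference-sample model
#'
#' Fits a multinomial logistic regression with a lasso (L1) penalty on
#' one-hot neighbour-state features, predicting the training sample's
#' own chromatin state labels at the sampled positions. Delegates the
#' fit to `glmnet` (`family = "multinomial"`, `alpha = 1`) at the
#' single fixed penalty `lambda`; binary features are not standardized
#' and per-state intercepts are included.
#'
#' States absent (or seen only once, too few for the multinomial fit)
#' in the training subsample are recorded as untrained and receive
#' probability exactly 0 from this model; positions carrying such
#' states are dropped from the fit.
#'
#' @param train_ann [state_annotation()] of the training sample.
#' @param feature_anns List of `L` [state_annotation()]s of the feature
#'   samples, in neighbour rank order.
#' @param positions Training positions (see [sample_positions()]).
#' @param lambda Lasso penalty, > 0.
#' @param seed Optional seed recorded with the model (the coordinate
#'   descent fit itself is deterministic).
#' @param thresh Convergence threshold passed to glmnet.
#' @return An object of class `StateModel` carrying the coefficient
#'   tensor, feature sample ids, trained/untrained states and metadata.
#'   `lambda_used` records the smallest penalty the coordinate-descent
#'   path reached: on (near-)separable training data the path saturates
#'   (fitted probabilities within machine tolerance of 0/1) before very
#'   small penalties, and the saturation-point coefficients are used.
#' @export
train_state_model <- function(train_ann, feature_anns, positions, lambda,
                              seed = NULL, thresh = 1e-7) {
  stopifnot(inherits(train_ann, "StateAnnotation"))
  if (lambda <= 0) stopf("lambda must be positive")
  alphabet <- train_ann$alphabet
  S <- length(alphabet)
  y <- train_ann$states[positions]
  if (anyNA(y)) stopf("training sample missing at %d position(s)", sum(is.na(y)))
  counts <- tabulate(y, nbins = S)
  trainable <- which(counts >= 2L)
  if (length(trainable) < 2) stopf("fewer than 2 distinct states among training labels")
  keep <- y %in% trainable
  X <- encode_features(feature_anns, positions[keep])
  yf <- factor(alphabet[y[keep]], levels = alphabet[trainable])
  # Coordinate descent needs warm starts to reach small penalties
  # reliably, so fit along a short decreasing lambda path ending at
  # the requested value and read coefficients off its last knot.
  # Rare states legitimately have few observations in a subsample;
  # glmnet's small-class caution is expected, not actionable.
  lambda_path <- sort(unique(c(
    exp(seq(log(max(0.5, lambda * 10)), log(lambda), length.out = 60)),
    lambda)), decreasing = TRUE)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, yf, family = "multinomial", alpha = 1,
                   lambda = lambda_path, standardize = FALSE,
                   intercept = TRUE, thresh = thresh, maxit = 1e6),
    warning = function(w) {
      # path truncation (saturation) is handled below via lambda_used
      if (grepl("fewer than 8|error code", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (length(fit$lambda) == 0) {
    stopf("model for '%s' did not converge at any penalty down to lambda = %g",
          train_ann$sample_id, lambda)
  }
  # On (near-)separable data the path saturates -- fitted probabilities
  # reach 0/1 within machine tolerance -- before tiny penalties; the
  # coefficients at the saturation point are the usable optimum, so take
  # the smallest penalty actually reached.
  knot <- which.min(fit$lambda)
  lambda_used <- fit$lambda[knot]
  K <- length(trainable)
  p <- ncol(X)
  beta <- matrix(0, p, K)
  a0 <- numeric(K)
  for (k in seq_len(K)) {
    a0[k] <- fit$a0[k, knot]
    beta[, k] <- as.numeric(fit$beta[[k]][, knot])
  }
  structure(list(
    train_sample_id = train_ann$sample_id,
    feature_sample_ids = vapply(feature_anns, function(a) a$sample_id, ""),
    alphabet = alphabet,
    trained_states = trainable,
    untrained_states = setdiff(seq_len(S), trainable),
    lambda = lambda,
    lambda_used = lambda_used,
    intercepts = a0,
    coefficients = beta,
    training_positions = positions,
    seed = seed
  ), class = "StateModel")
}

#' @export
print.StateModel <- function(x, ...) {
  cat(sprintf("StateModel for '%s': L = %d feature samples, lambda = %g, %d/%d states trained\n",
              x$train_sample_id, length(x$feature_sample_ids), x$lambda,
              length(x$trained_states), length(x$alphabet)))
  invisible(x)
}

#' Predict state probabilities with one model
#'
#' Applies a trained model to the one-hot features of its feature
#' samples at the requested positions. Probabilities are the softmax of
#' the per-state linear predictors; states untrained in this model get
#' probability 0.
#'
#' @param model A [train_state_model()] fit.
#' @param feature_anns List of [state_annotation()]s; sample ids must
#'   match `model$feature_sample_ids` in order.
#' @param positions Global bin indices to predict at.
#' @param sample_id Sample id recorded on the output (default the
#'   model's training sample).
#' @param genome Optional genome to attach to the output.
#' @return A [soft_annotation()] over `positions`.
#' @export
predict_state_probs <- function(model, feature_anns, positions,
                                sample_id = model$train_sample_id,
                                genome = NULL) {
  stopifnot(inherits(model, "StateModel"))
  ids <- unname(vapply(feature_anns, function(a) a$sample_id, ""))
  if (!identical(ids, unname(model$feature_sample_ids))) {
    stopf("feature samples (%s) do not match the model's feature samples (%s)",
          paste(ids, collapse = ","), paste(model$feature_sample_ids, collapse = ","))
  }
  X <- encode_features(feature_anns, positions)
  eta <- as.matrix(X %*% model$coefficients)
  eta <- sweep(eta, 2, model$intercepts, "+")
  eta <- eta - apply(eta, 1, max)  # numerical stability
  expeta <- exp(eta)
  probs_trained <- expeta / rowSums(expeta)
  probs <- matrix(0, nrow = length(positions), ncol = length(model$alphabet))
  probs[, model$trained_states] <- probs_trained
  if (is.null(genome) && !is.null(feature_anns[[1]]$genome)) {
    genome <- feature_anns[[1]]$genome
  }
  soft_annotation(sample_id, probs, model$alphabet, positions, genome)
}

#' Train models for a set of reference samples
#'
#' For each requested reference sample, determines its `L` nearest
#' reference samples by expression correlation (excluding itself) and
#' trains a [train_state_model()] on a fresh random position
#' subsample. Per-model seeds are derived deterministically from
#' `seed` and the sample's position in `reference_ids`.
#'
#' @param corr Correlation matrix over (at least) the reference samples
#'   (see [spearman_matrix()]).
#' @param annotations Named list of [state_annotation()]s for all
#'   reference samples.
#' @param reference_ids Ids of the reference compendium (candidate
#'   feature samples). Defaults to `names(annotations)`.
#' @param train_ids Ids to train models for (default all references).
#' @param L Number of feature samples per model.
#' @param lambda Lasso penalty.
#' @param n_positions Training positions per model.
#' @param seed Base seed.
#' @return Named list of `StateModel`s, keyed by training sample id.
#' @export
train_reference_models <- function(corr, annotations,
                                   reference_ids = names(annotations),
                                   train_ids = reference_ids,
                                   L = 5, lambda = 1e-4,
                                   n_positions = 3000, seed = 1) {
  genome <- annotations[[1]]$genome
  models <- vector("list", length(train_ids))
  names(models) <- train_ids
  for (id in train_ids) {
    nb <- rank_neighbors(id, corr, L, candidates = reference_ids)
    model_seed <- (seed + match(id, reference_ids)) %% .Machine$integer.max
    pos <- sample_positions(genome, n_positions, model_seed)
    models[[id]] <- train_state_model(annotations[[id]],
                                      annotations[nb$neighbor_ids],
                                      pos, lambda, seed = model_seed)
  }
  models
}

#' Ensemble prediction for a new sample
#'
#' Selects the `R` reference samples most correlated with the query by
#' expression, applies each of their trained models, and averages the
#' resulting probability matrices (unweighted arithmetic mean). The
#' hard annotation is obtained from the result with [hard_assign()].
#'
#' @param query_id Id of the query sample (a column of `corr`).
#' @param corr Correlation matrix covering the query and the reference
#'   samples.
#' @param models Named list of `StateModel`s keyed by reference id; a
#'   missing model for a selected reference is an error.
#' @param annotations Named list of reference [state_annotation()]s
#'   (source of the models' features).
#' @param R Ensemble size.
#' @param reference_ids Candidate reference ids (default the model
#'   names).
#' @param positions Bin indices to predict at (default all bins).
#' @return A [soft_annotation()] with attribute `references` naming the
#'   ensembled reference samples.
#' @export
ensemble_predict <- function(query_id, corr, models, annotations, R,
                             reference_ids = names(models),
                             positions = NULL) {
  genome <- annotations[[1]]$genome
  if (is.null(positions)) positions <- seq_len(genome$n_bins)
  nb <- rank_neighbors(query_id, corr, R, candidates = reference_ids)
  missing <- setdiff(nb$neighbor_ids, names(models))
  if (length(missing) > 0) {
    stopf("no trained model for selected reference(s): %s",
          paste(missing, collapse = ", "))
  }
  acc <- NULL
  for (id in nb$neighbor_ids) {
    m <- models[[id]]
    soft <- predict_state_probs(m, annotations[m$feature_sample_ids],
                                positions, sample_id = query_id,
                                genome = genome)
    acc <- if (is.null(acc)) soft$probs else acc + soft$probs
  }
  out <- soft_annotation(query_id, acc / R, annotations[[1]]$alphabet,
                         positions, genome)
  attr(out, "references") <- nb$neighbor_ids
  attr(out, "reference_correlations") <- nb$correlations
  out
}

#' Save / load trained models (JSON)
#'
#' Serializes a list of `StateModel`s to a portable JSON schema (ids,
#' penalty, coefficient tensor, training positions, seed) and restores
#' it. Probabilities predicted from a round-tripped model agree with
#' the original to full double precision.
#'
#' @param models Named list of `StateModel`s.
#' @param path JSON file path.
#' @return `path` invisibly for `write_models`; the model list for
#'   `read_models`.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(train_sample_id = m$train_sample_id,
         feature_sample_ids = m$feature_sample_ids,
         alphabet = m$alphabet,
         trained_states = m$trained_states,
         lambda = m$lambda,
         lambda_used = m$lambda_used,
         intercepts = m$intercepts,
         coefficients = m$coefficients,
         training_positions = m$training_positions,
         seed = m$seed)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(payload, function(m) {
    S <- length(m$alphabet)
    structure(list(
      train_sample_id = m$train_sample_id,
      feature_sample_ids = m$feature_sample_ids,
      alphabet = m$alphabet,
      trained_states = as.integer(m$trained_states),
      untrained_states = setdiff(seq_len(S), as.integer(m$trained_states)),
      lambda = m$lambda,
      lambda_used = m$lambda_used,
      intercepts = as.numeric(m$intercepts),
      coefficients = as.matrix(m$coefficients),
      training_positions = as.integer(m$training_positions),
      seed = m$seed
    ), class = "StateModel")
  })
  names(models) <- vapply(models, function(m) m$train_sample_id, "")
  models
}
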