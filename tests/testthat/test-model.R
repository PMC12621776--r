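test_that("position sampling is uniform without replacement and seed-reproducible", {
  g <- toy_genome(100)
  expect_equal(sample_positions(g, 100, 1), 1:100)
  expect_identical(sample_positions(g, 30, 42), sample_positions(g, 30, 42))
  expect_error(sample_positions(g, 101, 1), "exceeds")

  # Monte-Carlo inclusion frequency ~ n/bins within 3 SE
  n_rep <- 400
  hits <- numeric(100)
  for (s in seq_len(n_rep)) {
    idx <- sample_positions(g, 20, s)
    hits[idx] <- hits[idx] + 1
  }
  freq <- hits / n_rep
  se <- sqrt(0.2 * 0.8 / n_rep)
  expect_true(all(abs(freq - 0.2) < 3.5 * se))
})

test_that("one-hot encoding is slot-major with exactly one 1 per slot", {
  g <- toy_genome(2)
  a <- toy_ann(c(2L, 3L), n_states = 3, genome = g)
  X <- as.matrix(encode_features(list(a), 1:2))
  expect_equal(X[1, ], c(0, 1, 0))
  expect_equal(X[2, ], c(0, 0, 1))

  b <- toy_ann(c(3L, 1L), id = "b", n_states = 3, genome = g)
  X2 <- as.matrix(encode_features(list(b, a), 1))
  expect_equal(as.numeric(X2), c(0, 0, 1, 0, 1, 0))

  set.seed(8)
  g2 <- toy_genome(50)
  anns <- lapply(1:4, function(i) {
    toy_ann(sample(1:5, 50, TRUE), id = paste0("f", i), n_states = 5, genome = g2)
  })
  X3 <- encode_features(anns, 1:50)
  expect_true(all(Matrix::rowSums(X3) == 4))

  miss <- toy_ann(c(NA, 1L), n_states = 3, genome = g)
  expect_error(encode_features(list(miss), 1:2), "missing")
})

test_that("the lasso model recovers a copy relationship and rows are stochastic", {
  set.seed(19)
  g <- toy_genome(3000)
  freqs <- default_state_frequencies(18)
  states <- sample(1:18, 3000, TRUE, prob = freqs)
  train <- toy_ann(states, id = "train", n_states = 18, genome = g)
  f1 <- toy_ann(states, id = "f1", n_states = 18, genome = g)  # exact copy
  f2 <- toy_ann(sample(1:18, 3000, TRUE, prob = freqs), id = "f2",
                n_states = 18, genome = g)
  pos <- sample_positions(g, 2500, 4)
  m <- train_state_model(train, list(f1, f2), pos, lambda = 1e-4)
  soft <- predict_state_probs(m, list(f1, f2), pos)
  expect_gte(accuracy(hard_assign(soft), states, positions = pos), 0.99)
  expect_lt(max(abs(rowSums(soft$probs) - 1)), 1e-6)
})

test_that("a huge penalty shrinks all slopes to zero and predictions to class priors", {
  set.seed(23)
  g <- toy_genome(2000)
  states <- sample(1:4, 2000, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  train <- toy_ann(states, id = "t", n_states = 4, genome = g)
  feat <- toy_ann(sample(1:4, 2000, TRUE), id = "f", n_states = 4, genome = g)
  pos <- 1:2000
  m <- train_state_model(train, list(feat), pos, lambda = 10)
  expect_lt(max(abs(m$coefficients)), 1e-8)
  soft <- predict_state_probs(m, list(feat), 1:50)
  priors <- tabulate(states, 4) / 2000
  expect_equal(unname(soft$probs[1, ]), priors, tolerance = 1e-6)
})

test_that("states unseen in the training subsample get probability exactly zero", {
  set.seed(29)
  g <- toy_genome(500)
  states <- sample(c(1L, 2L, 3L), 500, TRUE)
  states[states == 3L] <- 1L           # state 3 never occurs
  states[1] <- 3L                      # ... except once (too few to train)
  train <- toy_ann(states, id = "t", n_states = 4, genome = g)
  feat <- toy_ann(sample(1:4, 500, TRUE), id = "f", n_states = 4, genome = g)
  m <- train_state_model(train, list(feat), 1:500, lambda = 1e-3)
  expect_setequal(m$untrained_states, c(3L, 4L))
  soft <- predict_state_probs(m, list(feat), 1:100)
  expect_true(all(soft$probs[, 3] == 0))
  expect_true(all(soft$probs[, 4] == 0))

  only_one <- toy_ann(rep(1L, 500), id = "o", n_states = 4, genome = g)
  expect_error(train_state_model(only_one, list(feat), 1:500, 1e-3),
               "fewer than 2 distinct states")
})

test_that("training is deterministic and prediction checks feature identity", {
  set.seed(37)
  g <- toy_genome(800)
  train <- toy_ann(sample(1:5, 800, TRUE), id = "t", n_states = 5, genome = g)
  f1 <- toy_ann(sample(1:5, 800, TRUE), id = "f1", n_states = 5, genome = g)
  f2 <- toy_ann(sample(1:5, 800, TRUE), id = "f2", n_states = 5, genome = g)
  m1 <- train_state_model(train, list(f1, f2), 1:800, 1e-3)
  m2 <- train_state_model(train, list(f1, f2), 1:800, 1e-3)
  expect_identical(m1$coefficients, m2$coefficients)
  p1 <- predict_state_probs(m1, list(f1, f2), 1:100)
  p2 <- predict_state_probs(m2, list(f1, f2), 1:100)
  expect_identical(p1$probs, p2$probs)
  expect_error(predict_state_probs(m1, list(f2, f1), 1:10), "do not match")
})

test_that("ensembling averages model probabilities (R = 1 degenerates to one model)", {
  comp <- cached_compendium(n_samples = 12, n_groups = 3, n_genes = 200,
                            n_bins = 800, annotation_noise = 0.1, seed = 3)
  corr <- spearman_matrix(preprocess_expression(comp$expression))
  models <- train_reference_models(corr, comp$annotations, L = 2,
                                   lambda = 1e-3, n_positions = 600, seed = 5)
  pos <- 1:200
  one <- ensemble_predict("sample01", corr, models, comp$annotations, R = 1,
                          positions = pos)
  ref1 <- attr(one, "references")[1]
  m <- models[[ref1]]
  direct <- predict_state_probs(m, comp$annotations[m$feature_sample_ids], pos)
  expect_equal(unname(one$probs), unname(direct$probs), tolerance = 1e-12)

  two <- ensemble_predict("sample01", corr, models, comp$annotations, R = 2,
                          positions = pos)
  ids <- attr(two, "references")
  manual <- (predict_state_probs(models[[ids[1]]],
                                 comp$annotations[models[[ids[1]]]$feature_sample_ids], pos)$probs +
             predict_state_probs(models[[ids[2]]],
                                 comp$annotations[models[[ids[2]]]$feature_sample_ids], pos)$probs) / 2
  expect_equal(unname(two$probs), unname(manual), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(two$probs) - 1)), 1e-6)
  expect_error(
    ensemble_predict("sample01", corr, models["sample02"], comp$annotations,
                     R = 3, reference_ids = setdiff(names(comp$annotations),
                                                    "sample01")),
    "no trained model")
})

test_that("hard assignment takes the argmax with low-index ties", {
  s <- soft_annotation("x", rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0)),
                       default_state_alphabet(3))
  expect_equal(hard_assign(s), c(1L, 1L))

  set.seed(41)
  p <- matrix(rexp(1000 * 18), 1000, 18)
  p <- p / rowSums(p)
  s2 <- soft_annotation("y", p, default_state_alphabet(18))
  expect_equal(hard_assign(s2), apply(p, 1, which.max))
})

test_that("models survive a JSON round-trip with identical predictions", {
  comp <- cached_compendium(n_samples = 12, n_groups = 3, n_genes = 200,
                            n_bins = 800, annotation_noise = 0.1, seed = 3)
  corr <- spearman_matrix(preprocess_expression(comp$expression))
  models <- train_reference_models(corr, comp$annotations,
                                   train_ids = c("sample01", "sample02"),
                                   L = 2, lambda = 1e-3, n_positions = 500,
                                   seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_models(models, f)
  back <- read_models(f)
  expect_identical(names(back), names(models))
  m <- models$sample01; b <- back$sample01
  expect_identical(b$feature_sample_ids, unname(m$feature_sample_ids))
  p1 <- predict_state_probs(m, comp$annotations[m$feature_sample_ids], 1:100)
  p2 <- predict_state_probs(b, comp$annotations[b$feature_sample_ids], 1:100)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
})
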