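test_that("calibration recovers r ~ 1 when labels are drawn from the predictions", {
  set.seed(61)
  n <- 20000
  p1 <- runif(n)
  probs <- cbind(p1, (1 - p1) * 0.6, (1 - p1) * 0.4)
  soft <- soft_annotation("s", probs, default_state_alphabet(3))
  labels <- vapply(seq_len(n), function(i) {
    sample.int(3, 1, prob = probs[i, ])
  }, integer(1))
  cc <- calibration_curve(soft, labels, state = 1, n_bins = 50)
  expect_gt(cc$r, 0.98)
  # mean predicted probabilities live inside their bins
  nz <- which(cc$counts > 0)
  expect_true(all(cc$mean_pred[nz] >= cc$edges[nz] - 1e-12))
  expect_true(all(cc$mean_pred[nz] <= cc$edges[nz + 1] + 1e-12))

  # all predictions in one bin -> undefined correlation, flagged
  flat <- soft_annotation("f", matrix(rep(c(0.5, 0.5), 10), 10, 2, byrow = TRUE),
                          default_state_alphabet(2))
  cf <- calibration_curve(flat, rep(1L, 10), state = 1)
  expect_true(cf$undefined)
})

test_that("probability-bin composition honours the count filter and group signal", {
  # one-hot predictions: surviving high bin is 100% the state itself
  n <- 600
  obs <- rep(c(1L, 2L), each = n / 2)
  probs <- cbind(obs == 1L, obs == 2L) * 1
  soft <- soft_annotation("s", probs, default_state_alphabet(2))
  out <- composition_by_probability(soft, obs, state = 1,
                                    grouping = c(1L, 2L), n_bins = 10,
                                    min_count = 100)
  expect_setequal(out$bin, c(1, 10))
  expect_equal(out$composition[out$bin == 10, 1], 1)

  # bins below min_count vanish
  out2 <- composition_by_probability(soft, obs, state = 1,
                                     grouping = c(1L, 2L), n_bins = 10,
                                     min_count = n)
  expect_length(out2$bin, 0)
  expect_true(out2$undefined)

  # constructed monotone toy: the higher the predicted probability of
  # state 1, the likelier a miss is its group-mate (state 2)
  set.seed(63)
  n <- 30000
  p1 <- runif(n, 0, 0.9)
  grouping <- c(1L, 1L, 2L)
  probs3 <- cbind(p1, 0.1, 0.9 - p1)
  obs3 <- vapply(seq_len(n), function(i) {
    sample.int(3, 1, prob = c(0, 0.1 + 0.8 * p1[i], 0.9 - 0.8 * p1[i]))
  }, integer(1))
  soft3 <- soft_annotation("m", probs3 / rowSums(probs3),
                           default_state_alphabet(3))
  out3 <- composition_by_probability(soft3, obs3, state = 1,
                                     grouping = grouping, n_bins = 20,
                                     min_count = 100)
  expect_gt(out3$r, 0.9)
})

test_that("group mismatch analysis matches hand cases and a sampling oracle", {
  grouping <- c(1L, 1L, 2L, 2L)
  # all mismatches within-group
  out <- group_mismatch_analysis(c(1L, 3L), c(2L, 4L), grouping, "all",
                                 quiescent_state = 4L)
  expect_equal(out$observed, 1)

  # degenerate two-state single-group alphabet
  out2 <- group_mismatch_analysis(c(1L, 2L, 1L), c(2L, 1L, 2L),
                                  grouping = c(1L, 1L), variant = "all",
                                  quiescent_state = 2L)
  expect_equal(out2$observed, 1)
  expect_equal(out2$expected, 1)
  expect_equal(out2$fold, 1)

  # 4-state toy: analytic expectation vs Monte-Carlo draws, both variants
  set.seed(67)
  n <- 400
  pred <- sample(1:4, n, TRUE, prob = c(0.1, 0.2, 0.3, 0.4))
  obs <- sample(1:4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  for (variant in c("all", "exclude_pred_quiescent")) {
    out3 <- group_mismatch_analysis(pred, obs, grouping, variant,
                                    quiescent_state = 4L)
    keep <- !is.na(pred) & pred != obs
    if (variant == "exclude_pred_quiescent") keep <- keep & pred != 4L
    x <- pred[keep]; y <- obs[keep]
    f <- tabulate(y, 4) / length(y)
    n_rep <- 4000
    draws <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      sampled <- vapply(x, function(px) {
        pr <- f
        if (variant == "all") pr[px] <- 0  # excludes the matching state
        sample.int(4, 1, prob = pr)
      }, integer(1))
      draws[r] <- mean(grouping[sampled] == grouping[x])
    }
    se <- stats::sd(draws) / sqrt(n_rep)
    expect_lt(abs(out3$expected - mean(draws)), 4 * se + 1e-8)
    expect_equal(out3$fold, out3$observed / out3$expected)
  }

  none <- group_mismatch_analysis(c(1L, 2L), c(1L, 2L), grouping, "all",
                                  quiescent_state = 4L)
  expect_true(none$undefined)
})

test_that("fold enrichment reproduces hand arithmetic and behaves at the edges", {
  g <- toy_genome(100)
  states <- rep(3L, 100)
  states[1:10] <- 1L
  ann <- toy_ann(states, n_states = 3, genome = g)

  # annotation = bins 1..5 -> fold for state 1 is (5/100)/((10/100)(5/100)) = 10
  iv <- interval_set(data.frame(chrom = "chr1", start = 0, end = 5 * 200))
  tab <- fold_enrichment(ann, iv, min_state_fraction = 0)
  expect_equal(tab$fold[1], 10)
  expect_equal(tab$fold[3], 0)  # disjoint state

  # whole-genome annotation -> fold 1 for every present state
  whole <- interval_set(data.frame(chrom = "chr1", start = 0, end = 100 * 200))
  tabw <- fold_enrichment(ann, whole, min_state_fraction = 0)
  expect_equal(tabw$fold[c(1, 3)], c(1, 1))

  # fold ~ 1 under independence (random states vs fixed annotation)
  set.seed(71)
  g2 <- toy_genome(50000)
  ann2 <- toy_ann(sample(1:2, 50000, TRUE, prob = c(0.3, 0.7)),
                  n_states = 2, genome = g2)
  half <- interval_set(data.frame(chrom = "chr1", start = 0, end = 25000 * 200))
  tab2 <- fold_enrichment(ann2, half)
  # SE of the joint fraction ~ sqrt(p(1-p)/n)/(p_s * p_a)
  se_fold <- sqrt(0.15 * 0.85 / 50000) / (0.3 * 0.5)
  expect_lt(abs(tab2$fold[1] - 1), 3.5 * se_fold)

  expect_error(fold_enrichment(ann, interval_set(data.frame(
    chrom = character(), start = numeric(), end = numeric()))), "empty")
})

test_that("soft fold enrichment truncates, renormalizes and reduces to the hard case", {
  g <- toy_genome(100)
  states <- rep(3L, 100); states[1:10] <- 1L
  ann <- toy_ann(states, n_states = 3, genome = g)
  onehot <- matrix(0, 100, 3); onehot[cbind(1:100, states)] <- 1
  soft <- soft_annotation("s", onehot, default_state_alphabet(3), genome = g)
  iv <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1000))
  hard_tab <- fold_enrichment(ann, iv, min_state_fraction = 0)
  soft_tab <- fold_enrichment_soft(soft, iv, min_state_fraction = 0)
  expect_equal(soft_tab$fold, hard_tab$fold)

  # truncation: (0.04, 0.96) -> (0, 1)
  p <- matrix(rep(c(0.04, 0.96), 10), 10, 2, byrow = TRUE)
  s2 <- soft_annotation("t", p, default_state_alphabet(2), genome = toy_genome(10))
  iv2 <- interval_set(data.frame(chrom = "chr1", start = 0, end = 400))
  tab2 <- fold_enrichment_soft(s2, iv2, floor = 0.05, min_state_fraction = 0)
  expect_equal(tab2$state_fraction, c(0, 1))

  # random soft annotation vs a brute-force probability-mass oracle
  set.seed(73)
  g3 <- toy_genome(400)
  pr <- matrix(rexp(400 * 4), 400, 4); pr <- pr / rowSums(pr)
  s3 <- soft_annotation("u", pr, default_state_alphabet(4), genome = g3)
  iv3 <- interval_set(data.frame(chrom = "chr1",
                                 start = c(0, 100 * 200),
                                 end = c(50 * 200, 300 * 200)))
  tab3 <- fold_enrichment_soft(s3, iv3, floor = 0.05, min_state_fraction = 0)
  prt <- pr; prt[prt < 0.05] <- 0; prt <- prt / rowSums(prt)
  cov <- c(rep(1, 50), rep(0, 50), rep(1, 200), rep(0, 100))
  oracle <- sapply(1:4, function(k) {
    (sum(prt[, k] * cov) / 400) / ((sum(prt[, k]) / 400) * (sum(cov) / 400))
  })
  expect_equal(tab3$fold, oracle, tolerance = 1e-10)
})

test_that("pairwise relationship matrices are symmetric with unit self-agreement", {
  g <- toy_genome(10)
  a <- toy_ann(rep(1:2, 5), "a", 3, g)
  b <- toy_ann(c(rep(1:2, 2), rep(2:1, 3)), "b", 3, g)  # agrees on bins 1-4... hand: 0.4? computed below
  agree <- pairwise_relationships(list(a = a, b = b, a2 = a), "agreement")
  expect_equal(diag(agree), c(a = 1, b = 1, a2 = 1))
  expect_equal(agree["a", "a2"], 1)
  expect_equal(agree["a", "b"], mean(a$states == b$states))
  expect_equal(agree, t(agree), tolerance = 1e-12)

  bin <- pairwise_relationships(list(a = a, b = b, a2 = a), "binary", state = 1)
  expect_equal(bin["a", "a2"], 1)
  expect_equal(bin["a", "b"],
               suppressWarnings(cor((a$states == 1) * 1, (b$states == 1) * 1)))

  set.seed(77)
  p1 <- matrix(rexp(10 * 3), 10, 3); p1 <- p1 / rowSums(p1)
  p2 <- matrix(rexp(10 * 3), 10, 3); p2 <- p2 / rowSums(p2)
  softs <- list(x = soft_annotation("x", p1, default_state_alphabet(3)),
                y = soft_annotation("y", p2, default_state_alphabet(3)))
  sp <- pairwise_relationships(softs, "soft", state = 2)
  expect_equal(sp["x", "y"], cor(p1[, 2], p2[, 2]))

  # constant (zero-variance) vectors are flagged, not reported as 0
  const <- toy_ann(rep(1L, 10), "const", 3, g)
  bin2 <- pairwise_relationships(list(a = a, const = const), "binary", state = 2)
  expect_true(is.na(bin2["a", "const"]))
})

test_that("group summaries split within/between pairs and score separation by AUPRC", {
  groups <- c(1, 1, 2, 2)
  m <- matrix(0.1, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.8
  diag(m) <- 1
  gs <- group_summary(m, groups)
  expect_equal(gs$within_mean, 0.85)
  expect_equal(gs$between_mean, 0.1)
  expect_equal(gs$difference, 0.75)
  expect_equal(gs$same_group_auprc, 1)

  # shuffled labels -> expected difference ~ 0
  set.seed(79)
  big <- matrix(runif(100), 10, 10)
  big[lower.tri(big)] <- t(big)[lower.tri(big)]
  diag(big) <- 1
  diffs <- replicate(300, group_summary(big, sample(rep(1:2, 5)))$difference)
  se <- sd(diffs) / sqrt(300)
  expect_lt(abs(mean(diffs)), 4 * se + 0.02)
  expect_error(group_summary(m, rep(1, 4)), "2 groups")
})

test_that("per-state signal means respect the coverage filter", {
  ann <- toy_ann(c(1L, 1L, 2L, 2L, 2L), n_states = 2)
  vals <- c(0.8, 0.8, 0.8, 0.8, 0.8)
  expect_equal(mean_signal_per_state(ann, vals, coverage = rep(5, 5)),
               c(0.8, 0.8))
  # low-coverage positions drop out
  vals2 <- c(0.2, 0.9, 0.5, 0.7, 0.1)
  covg <- c(3, 2, 3, 5, 1)
  expect_equal(mean_signal_per_state(ann, vals2, covg),
               c(0.2, mean(c(0.5, 0.7))))
  # a state with no qualifying position is NA
  expect_equal(mean_signal_per_state(ann, vals2, c(1, 1, 3, 3, 3))[1], NA_real_)

  # cross-sample averaging = mean of per-sample means
  ann2 <- toy_ann(c(2L, 2L, 1L, 1L, 1L), "b", 2)
  sig1 <- list(values = vals2, coverage = rep(5, 5))
  sig2 <- list(values = rev(vals2), coverage = rep(5, 5))
  got <- mean_signal_across_samples(list(ann, ann2), list(sig1, sig2))
  m1 <- mean_signal_per_state(ann, sig1$values, sig1$coverage)
  m2 <- mean_signal_per_state(ann2, sig2$values, sig2$coverage)
  expect_equal(got, rowMeans(cbind(m1, m2)))
})
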