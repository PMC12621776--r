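# Downstream analyses: calibration, near-miss structure of incorrect
# predictions, genomic fold enrichment, pairwise sample relationships,
# per-state signal averaging.

#' Probability calibration curve
#'
#' Groups positions into `n_bins` equally spaced probability bins over
#' [0, 1] by the predicted probability of `state`, and compares each
#' bin's mean predicted probability with the observed frequency of the
#' state among its positions. Empty bins are excluded; the Pearson
#' correlation over the remaining bins summarizes calibration.
#'
#' @param soft A [soft_annotation()].
#' @param obs Observed [state_annotation()] or state vector aligned
#'   with `soft$positions`.
#' @param state State index whose probability is assessed.
#' @param n_bins Number of equal probability bins (default 50).
#' @return List of class `CalibrationCurve` with `edges`, `mean_pred`,
#'   `obs_freq`, `counts` and `r` (Pearson; `NA` with a flag when fewer
#'   than 2 bins are non-empty).
#' @export
calibration_curve <- function(soft, obs, state, n_bins = 50) {
  stopifnot(inherits(soft, "SoftAnnotation"))
  y <- state_vector(obs)
  if (length(y) != nrow(soft$probs)) {
    if (!is.null(soft$positions) && length(y) >= max(soft$positions)) {
      y <- y[soft$positions]
    } else {
      stopf("observed states do not align with the soft annotation")
    }
  }
  p <- soft$probs[, state]
  ok <- !is.na(y)
  p <- p[ok]; y <- y[ok]
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mean_pred <- rep(NA_real_, n_bins)
  obs_freq <- rep(NA_real_, n_bins)
  nz <- which(counts > 0)
  mean_pred[nz] <- vapply(nz, function(b) mean(p[bin == b]), numeric(1))
  obs_freq[nz] <- vapply(nz, function(b) mean(y[bin == b] == state), numeric(1))
  r <- if (length(nz) >= 2) {
    suppressWarnings(stats::cor(mean_pred[nz], obs_freq[nz]))
  } else NA_real_
  structure(list(edges = edges, mean_pred = mean_pred, obs_freq = obs_freq,
                 counts = counts, r = r,
                 undefined = length(nz) < 2 || is.na(r)),
            class = "CalibrationCurve")
}

#' Observed-state composition across probability bins
#'
#' Bins positions by the predicted probability of `state` (`n_bins`
#' equal bins over [0, 1], bins with fewer than `min_count` positions
#' dropped) and tabulates the distribution of observed states within
#' each surviving bin. Additionally, restricted to positions where the
#' observed state differs from `state` (incorrect predictions), the
#' fraction of observed states falling in the predicted state's group
#' is correlated (Pearson) against the bins' mean predicted
#' probability, quantifying whether high confidence in a state also
#' signals biologically similar states.
#'
#' @inheritParams calibration_curve
#' @param grouping Integer state-to-group map (default
#'   [default_state_grouping()]).
#' @param n_bins Number of probability bins (default 100).
#' @param min_count Minimum positions per surviving bin (default 100).
#' @return List with `bin` (surviving bin ids), `mean_pred`, `counts`,
#'   `composition` (bins x S matrix of observed-state fractions),
#'   `same_group_fraction` (over incorrect predictions; `NA` when a bin
#'   has none) and `r`.
#' @export
composition_by_probability <- function(soft, obs, state,
                                       grouping = default_state_grouping(),
                                       n_bins = 100, min_count = 100) {
  stopifnot(inherits(soft, "SoftAnnotation"))
  y <- state_vector(obs)
  if (length(y) != nrow(soft$probs) && !is.null(soft$positions)) y <- y[soft$positions]
  p <- soft$probs[, state]
  ok <- !is.na(y)
  p <- p[ok]; y <- y[ok]
  S <- ncol(soft$probs)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- which(counts >= min_count)
  if (length(keep) == 0) {
    return(list(bin = integer(), mean_pred = numeric(), counts = integer(),
                composition = matrix(numeric(), 0, S),
                same_group_fraction = numeric(), r = NA_real_,
                undefined = TRUE))
  }
  comp <- t(vapply(keep, function(b) {
    tabulate(y[bin == b], nbins = S) / counts[b]
  }, numeric(S)))
  mean_pred <- vapply(keep, function(b) mean(p[bin == b]), numeric(1))
  same_group <- vapply(keep, function(b) {
    yy <- y[bin == b]
    wrong <- yy != state
    if (!any(wrong)) return(NA_real_)
    mean(grouping[yy[wrong]] == grouping[state])
  }, numeric(1))
  okb <- !is.na(same_group)
  r <- if (sum(okb) >= 2) {
    suppressWarnings(stats::cor(mean_pred[okb], same_group[okb]))
  } else NA_real_
  list(bin = keep, mean_pred = mean_pred, counts = counts[keep],
       composition = comp, same_group_fraction = same_group, r = r,
       undefined = is.na(r))
}

#' Near-miss structure of incorrect predictions
#'
#' Among positions where prediction and observation disagree, computes
#' the proportion whose observed state falls in the same biological
#' group as the predicted state, the proportion expected by chance,
#' and their ratio. The chance expectation is computed analytically:
#' a random state is drawn from the observed-state frequencies over
#' the retained positions, and the expectation is the mean probability
#' that the draw lands in the predicted state's group.
#'
#' Variants: `"all"` keeps every mismatched position and excludes the
#' predicted state itself from the sampling distribution (renormalized
#' per position); `"exclude_pred_quiescent"` first drops positions
#' whose prediction is the quiescent state, `"exclude_obs_quiescent"`
#' drops positions whose observation is quiescent; for both exclusion
#' variants the draw is from the retained positions' observed-state
#' frequencies without further exclusion.
#'
#' @param pred,obs [state_annotation()]s or state vectors.
#' @param grouping Integer state-to-group map.
#' @param variant One of `"all"`, `"exclude_pred_quiescent"`,
#'   `"exclude_obs_quiescent"`.
#' @param quiescent_state State index of the quiescent state (default
#'   the last state in the grouping).
#' @return List with `observed`, `expected`, `fold` and `n_positions`;
#'   all `NA` with a flag when no mismatched position survives.
#' @export
group_mismatch_analysis <- function(pred, obs,
                                    grouping = default_state_grouping(),
                                    variant = c("all", "exclude_pred_quiescent",
                                                "exclude_obs_quiescent"),
                                    quiescent_state = length(grouping)) {
  variant <- match.arg(variant)
  x <- state_vector(pred); y <- state_vector(obs)
  ok <- !is.na(x) & !is.na(y) & x != y
  if (variant == "exclude_pred_quiescent") ok <- ok & x != quiescent_state
  if (variant == "exclude_obs_quiescent") ok <- ok & y != quiescent_state
  if (!any(ok)) {
    return(list(observed = NA_real_, expected = NA_real_, fold = NA_real_,
                n_positions = 0L, undefined = TRUE))
  }
  x <- x[ok]; y <- y[ok]
  S <- length(grouping)
  f <- tabulate(y, nbins = S) / length(y)
  observed <- mean(grouping[y] == grouping[x])
  group_mass <- vapply(seq_len(S), function(g) {
    sum(f[grouping == grouping[g]])
  }, numeric(1))
  if (variant == "all") {
    # draw excludes the predicted state, renormalized per position
    num <- group_mass[x] - f[x]
    den <- 1 - f[x]
    expected <- mean(ifelse(den > 0, num / den, NA_real_), na.rm = TRUE)
  } else {
    expected <- mean(group_mass[x])
  }
  list(observed = observed, expected = expected,
       fold = observed / expected, n_positions = length(x),
       undefined = FALSE)
}

# Per-bin covered fraction (0..1) of the genome by a set of intervals.
# Overlapping intervals are merged first so coverage never exceeds 1.
bin_coverage <- function(genome, intervals) {
  cov <- numeric(genome$n_bins)
  bs <- genome$bin_size
  for (ci in seq_along(genome$chrom_names)) {
    iv <- intervals[intervals$chrom == genome$chrom_names[ci], , drop = FALSE]
    if (nrow(iv) == 0) next
    iv <- iv[order(iv$start), , drop = FALSE]
    len <- genome$chrom_lengths[ci]
    start <- pmax(iv$start, 0)
    end <- pmin(iv$end, len)
    keep <- start < end
    start <- start[keep]; end <- end[keep]
    if (length(start) == 0) next
    # merge overlapping/adjacent intervals
    ms <- numeric(0); me <- numeric(0)
    cs <- start[1]; ce <- end[1]
    for (i in seq_along(start)[-1]) {
      if (start[i] <= ce) {
        ce <- max(ce, end[i])
      } else {
        ms <- c(ms, cs); me <- c(me, ce)
        cs <- start[i]; ce <- end[i]
      }
    }
    ms <- c(ms, cs); me <- c(me, ce)
    for (i in seq_along(ms)) {
      b1 <- ms[i] %/% bs
      b2 <- (me[i] - 1) %/% bs
      idx <- genome$offsets[ci] + (b1:b2) + 1L
      bstart <- (b1:b2) * bs
      bend <- pmin(bstart + bs, len)
      ol <- pmin(me[i], bend) - pmax(ms[i], bstart)
      cov[idx] <- cov[idx] + ol / (bend - bstart)
    }
  }
  pmin(cov, 1)
}

#' Fold enrichment of chromatin states in an interval annotation
#'
#' For each state: (joint fraction of positions in the state AND
#' covered by the annotation) / (state fraction x annotation
#' fraction). A value of 1 means independence. Partially covered bins
#' contribute their covered fraction. Enrichments for states covering
#' less than `min_state_fraction` of the genome are suppressed (`NA`)
#' as unstable.
#'
#' @param ann A [state_annotation()].
#' @param intervals An [interval_set()] (or data.frame with `chrom`,
#'   `start`, `end`).
#' @param min_state_fraction Minimum genome fraction for a state's
#'   enrichment to be reported (default 1e-5, i.e. 0.001%).
#' @return data.frame of class `EnrichmentTable` with columns `state`,
#'   `state_fraction`, `annotation_fraction`, `joint_fraction`, `fold`.
#' @export
fold_enrichment <- function(ann, intervals, min_state_fraction = 1e-5) {
  stopifnot(inherits(ann, "StateAnnotation"))
  if (nrow(intervals) == 0) stopf("empty interval annotation")
  genome <- ann$genome
  cov <- bin_coverage(genome, intervals)
  s <- ann$states
  ok <- !is.na(s)
  n <- sum(ok)
  S <- length(ann$alphabet)
  state_frac <- tabulate(s[ok], nbins = S) / n
  annot_frac <- sum(cov[ok]) / n
  joint <- vapply(seq_len(S), function(k) sum(cov[ok][s[ok] == k]) / n, numeric(1))
  fold <- ifelse(state_frac > 0 & annot_frac > 0,
                 joint / (state_frac * annot_frac), NA_real_)
  fold[state_frac < min_state_fraction] <- NA_real_
  structure(data.frame(state = ann$alphabet, state_fraction = state_frac,
                       annotation_fraction = annot_frac,
                       joint_fraction = joint, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("EnrichmentTable", "data.frame"))
}

#' Fold enrichment from soft assignments
#'
#' As [fold_enrichment()], but states contribute probability mass
#' rather than hard counts. Probabilities below `floor` are truncated
#' to 0 and each position's remaining probabilities renormalized to
#' sum to 1 (positions losing all mass are dropped); low-probability
#' tails otherwise dilute the enrichments.
#'
#' @param soft A [soft_annotation()] carrying a genome.
#' @param intervals An [interval_set()].
#' @param floor Truncation threshold (default 0.05).
#' @param min_state_fraction As in [fold_enrichment()].
#' @return An `EnrichmentTable`.
#' @export
fold_enrichment_soft <- function(soft, intervals, floor = 0.05,
                                 min_state_fraction = 1e-5) {
  stopifnot(inherits(soft, "SoftAnnotation"))
  if (nrow(intervals) == 0) stopf("empty interval annotation")
  if (is.null(soft$genome)) stopf("soft annotation has no genome")
  probs <- soft$probs
  probs[probs < floor] <- 0
  rs <- rowSums(probs)
  keep <- rs > 0
  if (!any(keep)) stopf("all positions lost their probability mass at floor %g", floor)
  probs <- probs[keep, , drop = FALSE] / rs[keep]
  cov <- bin_coverage(soft$genome, intervals)[soft$positions][keep]
  n <- nrow(probs)
  state_frac <- colSums(probs) / n
  annot_frac <- sum(cov) / n
  joint <- colSums(probs * cov) / n
  fold <- ifelse(state_frac > 0 & annot_frac > 0,
                 joint / (state_frac * annot_frac), NA_real_)
  fold[state_frac < min_state_fraction] <- NA_real_
  structure(data.frame(state = soft$alphabet, state_fraction = state_frac,
                       annotation_fraction = annot_frac,
                       joint_fraction = joint, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("EnrichmentTable", "data.frame"))
}

#' Pairwise sample relationships
#'
#' Sample-by-sample matrix of one of three relationship measures:
#' `"agreement"` (fraction of positions with matching hard states,
#' unit diagonal), `"binary"` (Pearson correlation of one state's 0/1
#' presence vectors across positions) or `"soft"` (Pearson correlation
#' of one state's probability vectors). Positions may be subsampled
#' reproducibly.
#'
#' @param x Named list of [state_annotation()]s (`agreement`,
#'   `binary`) or [soft_annotation()]s (`soft`).
#' @param mode One of `"agreement"`, `"binary"`, `"soft"`.
#' @param state State index (required for the correlation modes).
#' @param n_positions Optional number of positions to subsample.
#' @param seed Seed for the subsample.
#' @return Symmetric matrix with sample ids as dimnames; zero-variance
#'   vectors yield `NA` entries in the correlation modes.
#' @export
pairwise_relationships <- function(x, mode = c("agreement", "binary", "soft"),
                                   state = NULL, n_positions = NULL, seed = 1) {
  mode <- match.arg(mode)
  n_samp <- length(x)
  ids <- names(x)
  if (is.null(ids)) ids <- vapply(x, function(a) a$sample_id, "")
  if (mode == "soft") {
    stopifnot(!is.null(state))
    vecs <- vapply(x, function(a) a$probs[, state], numeric(nrow(x[[1]]$probs)))
  } else {
    vecs <- vapply(x, function(a) state_vector(a), numeric(length(state_vector(x[[1]]))))
  }
  if (!is.null(n_positions)) {
    if (n_positions > nrow(vecs)) stopf("n_positions exceeds available positions")
    pos <- with_seed(seed, sort(sample.int(nrow(vecs), n_positions)))
    vecs <- vecs[pos, , drop = FALSE]
  }
  out <- matrix(NA_real_, n_samp, n_samp, dimnames = list(ids, ids))
  if (mode == "agreement") {
    for (i in seq_len(n_samp)) {
      out[i, i] <- 1
      for (j in seq_len(n_samp)[-seq_len(i)]) {
        out[i, j] <- out[j, i] <- pairwise_agreement(vecs[, i], vecs[, j])
      }
    }
  } else {
    if (mode == "binary") {
      stopifnot(!is.null(state))
      vecs <- (vecs == state) * 1
    }
    sds <- apply(vecs, 2, stats::sd, na.rm = TRUE)
    cm <- suppressWarnings(stats::cor(vecs, use = "pairwise.complete.obs"))
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
    diag(cm) <- ifelse(sds == 0, NA_real_, 1)
    out[, ] <- cm
  }
  out
}

#' Within- vs between-group summary of a relationship matrix
#'
#' Splits the off-diagonal entries of a pairwise relationship matrix by
#' whether the two samples share a group label, reports the within- and
#' between-group means and their difference, and quantifies how well
#' the relationship predicts same-group membership via [auprc()]
#' (pairs as items, same-group as positive).
#'
#' @param mat Symmetric relationship matrix (e.g. from
#'   [pairwise_relationships()]).
#' @param groups Group labels, one per sample (matrix order).
#' @return List with `within_mean`, `between_mean`, `difference`,
#'   `same_group_auprc`, and the pair count `n_pairs`.
#' @export
group_summary <- function(mat, groups) {
  n <- nrow(mat)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2) stopf("need at least 2 groups")
  pairs <- which(upper.tri(mat), arr.ind = TRUE)
  vals <- mat[pairs]
  same <- groups[pairs[, 1]] == groups[pairs[, 2]]
  ok <- !is.na(vals)
  vals <- vals[ok]; same <- same[ok]
  if (!any(same)) stopf("no within-group pair (all groups of size 1?)")
  list(within_mean = mean(vals[same]),
       between_mean = mean(vals[!same]),
       difference = mean(vals[same]) - mean(vals[!same]),
       same_group_auprc = auprc(vals, same),
       n_pairs = length(vals))
}

#' Mean signal per chromatin state
#'
#' Averages a per-position signal (e.g. CpG methylation level) within
#' each state, restricted to positions whose coverage meets
#' `min_coverage`. States with no qualifying position are `NA`.
#' Cross-sample summaries should average the per-sample per-state
#' means (see [mean_signal_across_samples()]).
#'
#' @param ann A [state_annotation()] or state vector.
#' @param values Per-position signal values.
#' @param coverage Per-position coverage (same length); positions with
#'   coverage below `min_coverage` are dropped.
#' @param min_coverage Minimum coverage (default 3).
#' @param n_states Number of states.
#' @return Numeric vector of per-state mean signal.
#' @export
mean_signal_per_state <- function(ann, values, coverage = NULL,
                                  min_coverage = 3, n_states = NULL) {
  s <- state_vector(ann)
  S <- n_states_of(ann, n_states)
  stopifnot(length(values) == length(s))
  ok <- !is.na(s) & !is.na(values)
  if (!is.null(coverage)) ok <- ok & coverage >= min_coverage
  out <- rep(NA_real_, S)
  if (any(ok)) {
    m <- tapply(values[ok], factor(s[ok], levels = seq_len(S)), mean)
    out <- as.numeric(m)
  }
  out
}

#' @rdname mean_signal_per_state
#' @param anns List of annotations (one per sample).
#' @param signals List of per-sample lists with elements `values` and
#'   `coverage`.
#' @export
mean_signal_across_samples <- function(anns, signals, min_coverage = 3,
                                       n_states = NULL) {
  per <- mapply(function(a, sig) {
    mean_signal_per_state(a, sig$values, sig$coverage, min_coverage, n_states)
  }, anns, signals)
  rowMeans(per, na.rm = TRUE)
}
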