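# Synthetic compendium generator: matched expression + chromatin-state
# data with latent sample groups, so the whole pipeline is exercisable
# without external data.

#' Default per-state genome frequencies
#'
#' A skewed, quiescent-dominant state distribution: half of the genome
#' in the final (quiescent) state and the remainder spread unevenly
#' over the other states, echoing the genome-wide composition of
#' 18-state segmentations where weak transcription and weak repression
#' are common and promoter/enhancer states are rare. For state counts
#' other than 18, a geometric decay over the non-quiescent states is
#' used.
#'
#' @param n_states Number of states (default 18).
#' @return Numeric vector of frequencies summing to 1.
#' @export
default_state_frequencies <- function(n_states = 18) {
  if (n_states == 18) {
    f <- c(0.015, 0.010, 0.008, 0.008, 0.045, 0.110, 0.008, 0.008, 0.020,
           0.015, 0.045, 0.025, 0.030, 0.004, 0.006, 0.015, 0.128, 0.500)
  } else {
    body <- 0.85 ^ seq_len(n_states - 1)
    f <- c(body / sum(body) * 0.5, 0.5)
  }
  f / sum(f)
}

#' Simulation configuration
#'
#' Parameters of the synthetic compendium generator. Samples fall into
#' latent groups; each group has a prototype chromatin-state track
#' drawn bin-wise from `state_base_frequencies`, and each sample copies
#' its group prototype except at a fraction `annotation_noise` of bins,
#' which are resampled from the base frequencies. Expression is
#' lognormal on the TPM scale: each gene has a baseline log2 mean, a
#' fraction `expression_signal_frac` of genes additionally carry
#' group-specific offsets, and samples add Gaussian noise on the log
#' scale, so that expression similarity predicts annotation similarity
#' within groups.
#'
#' @param n_samples Number of reference samples (default 30).
#' @param n_groups Number of latent groups (default 4; samples are
#'   assigned round-robin so groups are balanced).
#' @param n_genes Number of genes (default 500).
#' @param n_bins Number of 200-bp genome bins (default 5000; a single
#'   synthetic chromosome).
#' @param n_states Number of chromatin states (default 18).
#' @param state_base_frequencies Per-state genome frequencies (default
#'   [default_state_frequencies()]).
#' @param annotation_noise Per-bin probability that a sample's state is
#'   resampled from the base frequencies instead of copied from its
#'   group prototype (default 0.1).
#' @param expression_signal_frac Fraction of genes whose mean differs
#'   by group (default 0.2).
#' @param expression_noise_sd Standard deviation of per-sample log2
#'   expression noise (default 0.5).
#' @param group_effect_sd Standard deviation of the group-specific
#'   log2 offsets on signal genes (default 3, i.e. typical ~8-fold
#'   tissue-specific expression differences).
#' @param seed Integer seed; the generator is fully deterministic
#'   given the configuration.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_samples = 30, n_groups = 4, n_genes = 500,
                              n_bins = 5000, n_states = 18,
                              state_base_frequencies = default_state_frequencies(n_states),
                              annotation_noise = 0.1,
                              expression_signal_frac = 0.2,
                              expression_noise_sd = 0.5,
                              group_effect_sd = 3,
                              seed = 1) {
  if (n_groups > n_samples) stopf("more groups than samples")
  if (annotation_noise < 0 || annotation_noise > 1) stopf("annotation_noise must be in [0, 1]")
  if (expression_signal_frac < 0 || expression_signal_frac > 1) {
    stopf("expression_signal_frac must be in [0, 1]")
  }
  if (length(state_base_frequencies) != n_states) {
    stopf("state_base_frequencies must have length n_states")
  }
  if (any(state_base_frequencies < 0) || abs(sum(state_base_frequencies) - 1) > 1e-8) {
    stopf("state_base_frequencies must be non-negative and sum to 1")
  }
  structure(list(n_samples = n_samples, n_groups = n_groups,
                 n_genes = n_genes, n_bins = n_bins, n_states = n_states,
                 state_base_frequencies = state_base_frequencies,
                 annotation_noise = annotation_noise,
                 expression_signal_frac = expression_signal_frac,
                 expression_noise_sd = expression_noise_sd,
                 group_effect_sd = group_effect_sd, seed = seed),
            class = "SimulationConfig")
}

# Latent structure shared between the compendium and extra queries:
# group prototypes, per-gene baselines, group offsets. Deterministic
# from cfg$seed alone.
simulation_latents <- function(cfg) {
  with_seed(cfg$seed, {
    prototypes <- matrix(
      sample.int(cfg$n_states, cfg$n_bins * cfg$n_groups, replace = TRUE,
                 prob = cfg$state_base_frequencies),
      nrow = cfg$n_bins, ncol = cfg$n_groups)
    baseline <- stats::rnorm(cfg$n_genes, mean = 3, sd = 2)
    n_signal <- round(cfg$expression_signal_frac * cfg$n_genes)
    signal_genes <- sort(sample.int(cfg$n_genes, n_signal))
    offsets <- matrix(0, cfg$n_genes, cfg$n_groups)
    offsets[signal_genes, ] <- stats::rnorm(n_signal * cfg$n_groups,
                                            sd = cfg$group_effect_sd)
    list(prototypes = prototypes, baseline = baseline,
         signal_genes = signal_genes, offsets = offsets)
  })
}

# One sample's annotation and expression given the latents.
simulate_sample <- function(cfg, latents, group) {
  states <- latents$prototypes[, group]
  if (cfg$annotation_noise > 0) {
    flip <- stats::runif(cfg$n_bins) < cfg$annotation_noise
    if (any(flip)) {
      states[flip] <- sample.int(cfg$n_states, sum(flip), replace = TRUE,
                                 prob = cfg$state_base_frequencies)
    }
  }
  log_expr <- latents$baseline + latents$offsets[, group] +
    stats::rnorm(cfg$n_genes, sd = cfg$expression_noise_sd)
  list(states = states, tpm = 2 ^ log_expr)
}

#' Generate a synthetic reference compendium
#'
#' Draws a matched expression table (raw TPM scale) and per-sample
#' chromatin-state annotations under the group-structured generative
#' model described in [simulation_config()]. Fully deterministic given
#' the configuration (including its seed).
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `Compendium` with `expression`
#'   ([expression_table()], stage `raw_tpm`), `annotations` (named
#'   list of [state_annotation()]s), `groups` (named integer vector),
#'   `genome`, `prototypes` (bins x groups matrix of prototype
#'   states) and `config`.
#' @export
generate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  latents <- simulation_latents(cfg)
  genome <- binned_genome(c(chr1 = cfg$n_bins * 200), bin_size = 200)
  alphabet <- default_state_alphabet(cfg$n_states)
  groups <- rep_len(seq_len(cfg$n_groups), cfg$n_samples)
  ids <- sprintf("sample%02d", seq_len(cfg$n_samples))
  names(groups) <- ids
  tpm <- matrix(0, cfg$n_genes, cfg$n_samples,
                dimnames = list(sprintf("gene%04d", seq_len(cfg$n_genes)), ids))
  annotations <- vector("list", cfg$n_samples)
  names(annotations) <- ids
  with_seed(cfg$seed + 1L, {
    for (i in seq_len(cfg$n_samples)) {
      sm <- simulate_sample(cfg, latents, groups[i])
      tpm[, i] <- sm$tpm
      annotations[[i]] <- state_annotation(ids[i], sm$states, genome, alphabet)
    }
  })
  structure(list(expression = expression_table(tpm, "raw_tpm"),
                 annotations = annotations, groups = groups,
                 genome = genome, prototypes = latents$prototypes,
                 config = cfg),
            class = "Compendium")
}

#' @export
print.Compendium <- function(x, ...) {
  cat(sprintf("Synthetic compendium: %d samples in %d groups, %d genes, %d bins, %d states\n",
              x$config$n_samples, x$config$n_groups, x$config$n_genes,
              x$config$n_bins, x$config$n_states))
  invisible(x)
}

#' Generate a held-out query sample
#'
#' Draws one additional sample from a stated group's generative
#' process, sharing the compendium's latent prototypes and gene
#' effects. The true annotation is returned separately so it can be
#' withheld for benchmarking.
#'
#' @param compendium A [generate_compendium()] result.
#' @param group Group index of the new sample.
#' @param seed Seed for the query's own noise draws (default derived
#'   from the compendium seed).
#' @param sample_id Identifier for the query.
#' @return List with `expression` (named TPM vector), `annotation`
#'   (the withheld truth, a [state_annotation()]) and `group`.
#' @export
generate_query <- function(compendium, group, seed = NULL, sample_id = "query") {
  stopifnot(inherits(compendium, "Compendium"))
  cfg <- compendium$config
  if (!is_count(group) || group < 1 || group > cfg$n_groups) {
    stopf("unknown group %s (have %d groups)", format(group), cfg$n_groups)
  }
  if (is.null(seed)) seed <- cfg$seed + 1000L
  latents <- simulation_latents(cfg)
  sm <- with_seed(seed, simulate_sample(cfg, latents, group))
  tpm <- sm$tpm
  names(tpm) <- rownames(compendium$expression$values)
  list(expression = tpm,
       annotation = state_annotation(sample_id, sm$states,
                                     compendium$genome,
                                     compendium$annotations[[1]]$alphabet),
       group = as.integer(group))
}

#' Generate a methylation-like signal track
#'
#' Simulates a per-position signal with state-dependent means (values
#' clipped to [0, 1], Gaussian noise) and integer coverage drawn
#' uniformly from a range, for exercising [mean_signal_per_state()].
#'
#' @param ann A [state_annotation()].
#' @param state_means Per-state mean signal values in [0, 1].
#' @param noise_sd Gaussian noise standard deviation.
#' @param coverage_range Integer range (min, max) of per-position
#'   coverage.
#' @param seed Integer seed.
#' @return List with `values` and `coverage` vectors (NA values at
#'   missing bins).
#' @export
generate_signal_track <- function(ann, state_means, noise_sd = 0.05,
                                  coverage_range = c(1, 30), seed = 1) {
  s <- state_vector(ann)
  if (any(state_means < 0 | state_means > 1)) stopf("state means must be in [0, 1]")
  if (length(coverage_range) != 2 || coverage_range[1] > coverage_range[2] ||
      coverage_range[1] < 0) {
    stopf("invalid coverage range")
  }
  n <- length(s)
  with_seed(seed, {
    values <- rep(NA_real_, n)
    ok <- !is.na(s)
    values[ok] <- pmin(pmax(stats::rnorm(sum(ok), state_means[s[ok]], noise_sd), 0), 1)
    coverage <- sample(seq(coverage_range[1], coverage_range[2]), n, replace = TRUE)
    list(values = values, coverage = coverage)
  })
}
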