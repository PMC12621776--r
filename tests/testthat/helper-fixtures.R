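# Shared fixtures, built in code at test time.

toy_genome <- function(n_bins = 10, bin_size = 200, chrom = "chr1") {
  lengths <- stats::setNames(n_bins * bin_size, chrom)
  binned_genome(lengths, bin_size)
}

toy_ann <- function(states, id = "s", n_states = max(states, na.rm = TRUE),
                    genome = toy_genome(length(states))) {
  state_annotation(id, states, genome, default_state_alphabet(n_states))
}

# One lazily built compendium per configuration, shared across tests.
.comp_cache <- new.env(parent = emptyenv())
cached_compendium <- function(..., seed = 1) {
  key <- paste(deparse(list(..., seed)), collapse = "")
  if (is.null(.comp_cache[[key]])) {
    .comp_cache[[key]] <- generate_compendium(simulation_config(..., seed = seed))
  }
  .comp_cache[[key]]
}

# Independent stepwise-interpolation AUPRC oracle: explicit loop over
# unique thresholds, straight from the definition.
auprc_oracle <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    called <- scores >= t
    precision <- sum(labels[called]) / sum(called)
    recall <- sum(labels[called]) / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Independent AUROC oracle: all positive-negative pairs compared.
auroc_oracle <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
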