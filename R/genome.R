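#' Binned genome
#'
#' Partitions a set of chromosomes into consecutive fixed-width bins
#' ("positions"). Chromatin-state segmentations are defined at 200-bp
#' resolution, so the default bin size is 200 bp. Bins are indexed by a
#' single global 1-based index running through the chromosomes in the
#' order given; the last bin of a chromosome may be shorter than
#' `bin_size` and is treated as a full-weight position.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in
#'   base pairs; names are the chromosome identifiers and fix the
#'   chromosome order.
#' @param bin_size Bin width in base pairs (default 200).
#' @return An object of class `BinnedGenome` with fields `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `bins_per_chrom`, `offsets` (global
#'   index of the bin before each chromosome's first bin) and `n_bins`.
#' @examples
#' g <- binned_genome(c(chr1 = 1000, chr2 = 500))
#' g$n_bins
#' @export
binned_genome <- function(chrom_lengths, bin_size = 200) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stopf("chrom_lengths must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stopf("duplicate chromosome names")
  }
  if (!is_count(bin_size) || bin_size <= 0) stopf("bin_size must be a positive integer")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  bins <- as.integer(ceiling(chrom_lengths / bin_size))
  structure(list(
    chrom_names = names(chrom_lengths),
    chrom_lengths = as.numeric(chrom_lengths),
    bin_size = as.integer(bin_size),
    bins_per_chrom = bins,
    offsets = c(0L, cumsum(bins)[-length(bins)]),
    n_bins = sum(bins)
  ), class = "BinnedGenome")
}

#' @export
print.BinnedGenome <- function(x, ...) {
  cat(sprintf("BinnedGenome: %d chromosome(s), %d bins of %d bp\n",
              length(x$chrom_names), x$n_bins, x$bin_size))
  invisible(x)
}

#' Global bin index of genomic coordinates
#'
#' Maps (chromosome, 0-based base-pair position) to the global 1-based
#' bin index. The mapping is strictly increasing in (chromosome order,
#' position) and invertible via [bin_ranges()].
#'
#' @param genome A [binned_genome()].
#' @param chrom Chromosome names (recycled with `pos`).
#' @param pos 0-based base-pair positions.
#' @return Integer vector of global bin indices.
#' @export
bin_index <- function(genome, chrom, pos) {
  ci <- match(chrom, genome$chrom_names)
  if (anyNA(ci)) stopf("unknown chromosome: %s", paste(unique(chrom[is.na(ci)]), collapse = ", "))
  if (any(pos < 0) || any(pos >= genome$chrom_lengths[ci])) {
    stopf("position out of chromosome range")
  }
  genome$offsets[ci] + pos %/% genome$bin_size + 1L
}

#' Coordinates of genome bins
#'
#' Inverse of [bin_index()]: returns the chromosome and 0-based
#' half-open interval of each requested bin (BED convention). The last
#' bin of a chromosome is clipped at the chromosome end.
#'
#' @param genome A [binned_genome()].
#' @param index Global bin indices; default all bins.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
bin_ranges <- function(genome, index = NULL) {
  if (is.null(index)) index <- seq_len(genome$n_bins)
  index <- as.integer(index)
  if (any(index < 1L) || any(index > genome$n_bins)) stopf("bin index out of range")
  ci <- findInterval(index - 1L, genome$offsets)
  within_chr <- index - 1L - genome$offsets[ci]
  start <- within_chr * genome$bin_size
  end <- pmin(start + genome$bin_size, genome$chrom_lengths[ci])
  data.frame(chrom = genome$chrom_names[ci], start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Standard 18-state alphabet
#'
#' The state names of the widely used Roadmap Epigenomics 18-state
#' ChromHMM model, which is the default alphabet throughout the
#' package. For other state counts generic names `S1..Sn` are returned.
#'
#' @param n_states Number of states (default 18).
#' @return Character vector of state names.
#' @export
default_state_alphabet <- function(n_states = 18) {
  if (n_states == 18) {
    c("1_TssA", "2_TssFlnk", "3_TssFlnkU", "4_TssFlnkD", "5_Tx", "6_TxWk",
      "7_EnhG1", "8_EnhG2", "9_EnhA1", "10_EnhA2", "11_EnhWk", "12_ZNF/Rpts",
      "13_Het", "14_TssBiv", "15_EnhBiv", "16_ReprPC", "17_ReprPCWk",
      "18_Quies")
  } else {
    paste0("S", seq_len(n_states))
  }
}

#' Biological grouping of the 18 chromatin states
#'
#' Groups the 18-state alphabet into seven biologically interpretable
#' clusters: TSS-related (states 1-4), transcription (5-6), enhancer
#' (7-11), H3K9me3-associated (12-13), bivalent (14-15), Polycomb
#' repressed (16-17) and quiescent (18). Used to score "near-miss"
#' predictions where the predicted state differs from the observed one
#' but shares its biological interpretation.
#'
#' @return Integer vector of length 18 mapping each state index to a
#'   group id; names give the group labels.
#' @export
default_state_grouping <- function() {
  groups <- c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 5L, 5L,
              6L, 6L, 7L)
  names(groups) <- c("TSS", "TSS", "TSS", "TSS", "Tx", "Tx", "Enh", "Enh",
                     "Enh", "Enh", "Enh", "H3K9me3", "H3K9me3", "Biv",
                     "Biv", "ReprPC", "ReprPC", "Quies")
  groups
}
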