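#' Read a dense chromatin-state segmentation (BED4)
#'
#' Reads a ChromHMM-style dense segmentation: a 4+ column BED file with
#' chrom, start, end (0-based half-open) and state name. Record
#' boundaries must fall on bin boundaries (the end may instead coincide
#' with the chromosome end). Each covered bin receives the record's
#' state; bins not covered by any record are missing; records that
#' overlap are rejected.
#'
#' @param path Path to the BED file.
#' @param genome A [binned_genome()].
#' @param sample_id Sample identifier for the annotation; defaults to
#'   the file name without extension.
#' @param alphabet Ordered state names; labels outside it are an error.
#' @param skip_unknown_chroms If `TRUE`, records on chromosomes absent
#'   from `genome` are silently dropped instead of raising an error.
#' @return A [state_annotation()].
#' @export
read_segmentation <- function(path, genome, sample_id = NULL,
                              alphabet = default_state_alphabet(),
                              skip_unknown_chroms = FALSE) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  states <- rep(NA_integer_, genome$n_bins)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(state_annotation(sample_id, states, genome, alphabet))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stopf("%s: segmentation BED needs at least 4 columns", path)
  chrom <- bed[[1]]; start <- as.numeric(bed[[2]]); end <- as.numeric(bed[[3]])
  label <- as.character(bed[[4]])
  ci <- match(chrom, genome$chrom_names)
  if (anyNA(ci)) {
    if (!skip_unknown_chroms) {
      stopf("%s: unknown chromosome '%s' (line %d)", path,
            chrom[which(is.na(ci))[1]], which(is.na(ci))[1])
    }
    keep <- !is.na(ci)
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    label <- label[keep]; ci <- ci[keep]
    if (length(ci) == 0) return(state_annotation(sample_id, states, genome, alphabet))
  }
  si <- match(label, alphabet)
  if (anyNA(si)) {
    stopf("%s: unknown state label '%s' (line %d)", path,
          label[which(is.na(si))[1]], which(is.na(si))[1])
  }
  bs <- genome$bin_size
  len <- genome$chrom_lengths[ci]
  if (any(start < 0) || any(end <= start) || any(end > len)) {
    stopf("%s: malformed or out-of-range interval", path)
  }
  if (any(start %% bs != 0)) stopf("%s: interval start not a multiple of bin size", path)
  bad_end <- end %% bs != 0 & end != len
  if (any(bad_end)) {
    stopf("%s: interval end %d not a bin multiple nor the chromosome end (line %d)",
          path, end[which(bad_end)[1]], which(bad_end)[1])
  }
  first <- genome$offsets[ci] + start %/% bs + 1L
  last <- genome$offsets[ci] + as.integer(ceiling(end / bs))
  for (i in seq_along(first)) {
    bins <- first[i]:last[i]
    if (any(!is.na(states[bins]))) stopf("%s: overlapping records (line %d)", path, i)
    states[bins] <- si[i]
  }
  state_annotation(sample_id, states, genome, alphabet)
}

#' Write a chromatin-state segmentation (BED4)
#'
#' Emits maximal runs of identical state as single BED records, sorted
#' by chromosome (genome order) and start. Missing bins produce no
#' record.
#'
#' @param ann A [state_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(ann, path) {
  stopifnot(inherits(ann, "StateAnnotation"))
  genome <- ann$genome
  rows <- vector("list", length(genome$chrom_names))
  for (ci in seq_along(genome$chrom_names)) {
    nb <- genome$bins_per_chrom[ci]
    s <- ann$states[genome$offsets[ci] + seq_len(nb)]
    r <- rle(ifelse(is.na(s), 0L, s))
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0L
    if (!any(keep)) next
    start <- starts_bin[keep] * genome$bin_size
    end <- pmin(ends_bin[keep] * genome$bin_size, genome$chrom_lengths[ci])
    rows[[ci]] <- data.frame(chrom = genome$chrom_names[ci], start = start,
                             end = end, name = ann$alphabet[r$values[keep]],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene expression table
#'
#' A genes-by-samples matrix of expression values together with its
#' processing stage: `raw_tpm` (transcripts per million as input),
#' `quantile_normalized`, or `log2` (log2 of normalized values + 1).
#'
#' @param values Numeric matrix with rownames = gene ids and
#'   colnames = sample ids.
#' @param stage Processing stage the values are at.
#' @return An object of class `ExpressionTable`.
#' @export
expression_table <- function(values, stage = c("raw_tpm", "quantile_normalized", "log2")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("expression values need gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (stage != "log2" && any(values < 0)) stopf("negative expression value at stage '%s'", stage)
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), stage = stage),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d samples (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Read an expression table (TSV)
#'
#' Expects a tab-separated file with a header row: a gene-id column
#' (first) followed by one numeric column per sample. Values are taken
#' to be raw TPM.
#'
#' @param path Path to the TSV file.
#' @return An [expression_table()] at stage `raw_tpm`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("%s: expected a gene-id column plus sample columns", path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stopf("%s: duplicate gene id '%s'", path, genes[duplicated(genes)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stopf("%s: non-numeric expression values", path)
  if (any(is.na(vals))) stopf("%s: missing expression values", path)
  if (any(vals < 0)) stopf("%s: negative expression values", path)
  rownames(vals) <- genes
  expression_table(vals, "raw_tpm")
}

#' Write an expression table (TSV)
#'
#' @param expr An [expression_table()].
#' @param path Output file path.
#' @param gene_column Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, gene_column = "gene_id") {
  stopifnot(inherits(expr, "ExpressionTable"))
  df <- data.frame(expr$gene_ids, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_column, expr$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interval annotation (BED)
#'
#' Reads a 3+ column BED file of 0-based half-open intervals (e.g. CpG
#' islands, TSS windows, peak calls) for enrichment analyses.
#' Intervals are sorted per chromosome on load.
#'
#' @param path Path to the BED file.
#' @param name Annotation name; defaults to the file name.
#' @return An object of class `IntervalSet`: a data.frame with columns
#'   `chrom`, `start`, `end` and attribute `name`.
#' @export
read_intervals <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    iv <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 3)) {
      stopf("%s: malformed BED line %d (fewer than 3 fields)", path, which(nfield < 3)[1])
    }
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    bad <- is.na(start) | is.na(end) | start < 0 | start >= end
    if (any(bad)) stopf("%s: malformed BED line %d", path, which(bad)[1])
    iv <- data.frame(chrom = vapply(parts, `[[`, "", 1L), start = start,
                     end = end, stringsAsFactors = FALSE)
    iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
    rownames(iv) <- NULL
  }
  interval_set(iv, name)
}

#' Construct an interval set
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param name Annotation name.
#' @return An `IntervalSet`.
#' @export
interval_set <- function(intervals, name = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stopf("interval with start >= end")
  intervals <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(intervals, class = c("IntervalSet", "data.frame"), name = name)
}

#' Write per-state probability tracks (bedGraph)
#'
#' Writes one bedGraph file per state, with the per-bin probability of
#' that state as the track value. File names are the state names with
#' path-unsafe characters replaced.
#'
#' @param soft A [soft_annotation()] carrying a genome.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_soft_tracks <- function(soft, dir) {
  stopifnot(inherits(soft, "SoftAnnotation"))
  if (is.null(soft$genome)) stopf("soft annotation has no genome; cannot emit coordinates")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  coords <- bin_ranges(soft$genome, soft$positions)
  paths <- character(ncol(soft$probs))
  for (s in seq_len(ncol(soft$probs))) {
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "-", soft$alphabet[s]), ".bedGraph")
    paths[s] <- file.path(dir, fname)
    df <- data.frame(coords$chrom, coords$start, coords$end,
                     format(soft$probs[, s], digits = 12, scientific = FALSE,
                            trim = TRUE))
    utils::write.table(df, paths[s], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read gene records from a GTF annotation
#'
#' Extracts gene-level records (id, location, strand, biotype) from a
#' GTF file such as a GENCODE release, for use with [filter_genes()].
#' Delegates parsing to `rtracklayer::import`.
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (start/end 1-based as in GTF).
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("read_gene_annotation requires the rtracklayer package")
  }
  df <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
  biotype_col <- intersect(c("gene_type", "gene_biotype"), names(df))[1]
  if (is.na(biotype_col)) stopf("%s: no gene biotype attribute found", path)
  data.frame(gene_id = df$gene_id,
             chrom = as.character(df$seqnames),
             start = df$start,
             end = df$end,
             strand = as.character(df$strand),
             biotype = df[[biotype_col]],
             stringsAsFactors = FALSE)
}
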