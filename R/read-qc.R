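#' Build an adapter set closed under reverse complement
#'
#' @param sequences Character vector of adapter/contaminant sequences;
#'   defaults to the four screened Illumina 50-mers
#'   ([illumina_adapters()]).
#' @return Character vector containing the sequences and their reverse
#'   complements, class `"adapter_set"`.
#' @export
adapter_set <- function(sequences = illumina_adapters()) {
  if (length(sequences) == 0L) stop("adapter set must be non-empty")
  structure(unique(c(sequences, revcomp(sequences))), class = "adapter_set")
}

#' Adapter filter decision for reads
#'
#' A read is dropped iff any adapter (the set is closed under reverse
#' complement) occurs as an exact substring of its sequence.
#'
#' @param seqs Character vector of read sequences.
#' @param adapters An [adapter_set()].
#' @return Logical vector: `TRUE` = drop.
#' @export
filter_adapters <- function(seqs, adapters = adapter_set()) {
  drop <- rep(FALSE, length(seqs))
  for (a in adapters) {
    drop <- drop | grepl(a, seqs, fixed = TRUE)
  }
  drop
}

#' Truncate reads at the first low-quality base
#'
#' Removes all bases at and after the first position whose Phred score is
#' less than or equal to `threshold` (default Q15).  The quality string is
#' truncated in lockstep.  A read whose first base triggers becomes empty.
#'
#' @param seqs Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (same lengths).
#' @param threshold Phred score threshold (inclusive).
#' @return List with truncated `seqs` and `quals`.
#' @export
quality_truncate <- function(seqs, quals, threshold = 15L) {
  stopifnot(length(seqs) == length(quals), all(nchar(seqs) == nchar(quals)))
  cutpoint <- vapply(quals, function(q) {
    sc <- phred_scores(q)
    bad <- which(sc <= threshold)
    if (length(bad) == 0L) length(sc) + 1L else bad[1]
  }, integer(1), USE.NAMES = FALSE)
  list(seqs = substr(seqs, 1L, cutpoint - 1L),
       quals = substr(quals, 1L, cutpoint - 1L))
}

#' Quality-control a paired-end library
#'
#' Applies the adapter filter and quality truncation to both mates.  A pair
#' is dropped if either mate contains an adapter or is shorter than
#' `min_length` after truncation; otherwise both (truncated) mates are
#' kept, preserving input order and mate pairing.
#'
#' @param mate1,mate2 data.frames with columns `id`, `seq`, `qual`
#'   (record-aligned, as from [read_fastq()]), or paths to FASTQ files.
#' @param adapters An [adapter_set()].
#' @param quality_threshold Phred truncation threshold (inclusive).
#' @param min_length Minimum post-trim length of each mate (default 20, so
#'   a typical assembly k-mer still fits).
#' @return List with `mate1`, `mate2` (surviving trimmed reads) and `stats`:
#'   data.frame with `reads_in`, `reads_out`, `dropped_adapter`,
#'   `dropped_short`, `mean_length_out`.  `reads_out + dropped_adapter +
#'   dropped_short == reads_in` (pairs counted once).
#' @export
qc_library <- function(mate1, mate2, adapters = adapter_set(),
                       quality_threshold = 15L, min_length = 20L) {
  if (is.character(mate1)) mate1 <- read_fastq(mate1)
  if (is.character(mate2)) mate2 <- read_fastq(mate2)
  if (nrow(mate1) != nrow(mate2)) {
    stop("malformed input: mate files have different record counts")
  }
  n <- nrow(mate1)
  adapter_hit <- filter_adapters(mate1$seq, adapters) |
    filter_adapters(mate2$seq, adapters)
  t1 <- quality_truncate(mate1$seq, mate1$qual, quality_threshold)
  t2 <- quality_truncate(mate2$seq, mate2$qual, quality_threshold)
  short <- nchar(t1$seqs) < min_length | nchar(t2$seqs) < min_length
  keep <- !adapter_hit & !short
  out1 <- data.frame(id = mate1$id[keep], seq = t1$seqs[keep],
                     qual = t1$quals[keep], stringsAsFactors = FALSE,
                     row.names = NULL)
  out2 <- data.frame(id = mate2$id[keep], seq = t2$seqs[keep],
                     qual = t2$quals[keep], stringsAsFactors = FALSE,
                     row.names = NULL)
  stats <- data.frame(
    reads_in = n,
    reads_out = sum(keep),
    dropped_adapter = sum(adapter_hit),
    dropped_short = sum(short & !adapter_hit),
    mean_length_out = if (any(keep)) {
      mean(c(nchar(out1$seq), nchar(out2$seq)))
    } else NA_real_
  )
  list(mate1 = out1, mate2 = out2, stats = stats)
}

#' Quality-control every library of a simulated experiment
#'
#' @param sim Output of [simulate_reads()].
#' @param ... Passed to [qc_library()].
#' @return Named list per library of [qc_library()] results, plus an
#'   attached `stats` data.frame (one row per library).
#' @export
qc_experiment <- function(sim, ...) {
  out <- lapply(sim, function(lib) qc_library(lib$mate1, lib$mate2, ...))
  stats <- do.call(rbind, lapply(out, `[[`, "stats"))
  stats <- cbind(library_id = names(sim), stats, row.names = NULL)
  attr(out, "stats") <- stats
  out
}

#' Pooled read sequences of a QC'd experiment
#'
#' Convenience accessor: per-library character vectors of both mates'
#' surviving sequences, ready for [sweep_assemblies()].
#'
#' @param qc Output of [qc_experiment()].
#' @return Named list of character vectors.
#' @export
qc_read_sets <- function(qc) {
  lapply(qc, function(lib) c(lib$mate1$seq, lib$mate2$seq))
}
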