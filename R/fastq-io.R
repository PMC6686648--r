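#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper over [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file into a data.frame
#'
#' @param path Path to an uncompressed or gzipped FASTQ file (Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual` (character).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Phred scores of a quality string
#'
#' @param qual Single Phred+33 quality string.
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}
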