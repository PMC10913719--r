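#' Read/write FASTA and FASTQ
#'
#' Thin wrappers around Biostrings. Reads are serialized as Phred+33 FASTQ;
#' the hidden truth labels are never written to FASTQ -- use
#' [write_truth_tsv()] for the sidecar.
#'
#' @param sequences Named character vector of sequences.
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param path File path (uncompressed).
#' @return Writers return `path` invisibly. `read_fasta()` returns a named
#'   character vector; `read_fastq()` a read tibble (no `truth` column).
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  assert_reads(reads)
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual)))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(read_id = names(x),
         seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}

#' Truth-label sidecar TSV
#'
#' @param reads Read tibble with a `truth` column.
#' @param path File path.
#' @return `write_truth_tsv()` returns `path` invisibly; `read_truth_tsv()`
#'   a tibble with `read_id`, `truth`.
#' @export
write_truth_tsv <- function(reads, path) {
  readr::write_tsv(reads[, c("read_id", "truth")], path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
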