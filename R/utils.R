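# Internal helpers shared across modules.

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "seq", "qual") %in% names(reads))) {
    stop("`", arg, "` must be a data frame with columns read_id, seq, qual",
         call. = FALSE)
  }
  invisible(reads)
}

# Derive a stream-specific 32-bit seed from a base seed, so independent
# stages of one run do not share RNG streams.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
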