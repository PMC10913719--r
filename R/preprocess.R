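#' Sliding-window quality trimming
#'
#' Scans each read's quality string left to right in windows of `window`
#' bases; at the first window whose mean Phred quality falls below
#' `min_mean_q` the read is truncated at that window's start. Reads whose
#' kept length is at most half the original length are discarded.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`, ...).
#' @param window Window width in bases.
#' @param min_mean_q Minimum mean window quality.
#' @return The read tibble with trimmed `seq`/`qual`, failing reads removed.
#' @export
quality_trim <- function(reads, window = 4, min_mean_q = 20) {
  assert_reads(reads)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (nrow(reads) == 0) return(reads)
  keep_len <- cpp_window_trim(reads$qual, as.integer(window), min_mean_q)
  orig_len <- nchar(reads$seq)
  survive <- keep_len > orig_len / 2
  out <- reads[survive, ]
  kl <- keep_len[survive]
  trim <- kl < nchar(out$seq)
  out$seq[trim] <- substr(out$seq[trim], 1L, kl[trim])
  out$qual[trim] <- substr(out$qual[trim], 1L, kl[trim])
  out
}

#' Remove an exact adapter prefix/suffix
#'
#' Models adapter trimming as removal of an exact occurrence of the adapter
#' string at the start or end of a read.
#'
#' @param reads Read tibble.
#' @param adapter Adapter sequence, or `NULL` for a no-op.
#' @return The read tibble with adapters stripped.
#' @export
trim_adapters <- function(reads, adapter = NULL) {
  assert_reads(reads)
  if (is.null(adapter) || nrow(reads) == 0) return(reads)
  alen <- nchar(adapter)
  pre <- startsWith(reads$seq, adapter)
  reads$seq[pre] <- substring(reads$seq[pre], alen + 1L)
  reads$qual[pre] <- substring(reads$qual[pre], alen + 1L)
  suf <- endsWith(reads$seq, adapter)
  n <- nchar(reads$seq[suf])
  reads$seq[suf] <- substr(reads$seq[suf], 1L, n - alen)
  reads$qual[suf] <- substr(reads$qual[suf], 1L, n - alen)
  reads
}

#' Alignment-free reference depletion
#'
#' A read is removed iff the fraction of its canonical k-mers present in the
#' reference k-mer set is at least `min_hit_fraction`. This preserves the
#' deplete-by-reference contract of the workflow without shipping an aligner.
#'
#' @param reads Read tibble.
#' @param reference_sequences Character vector of reference sequences (or a
#'   prebuilt k-mer set from [kmer_set()]).
#' @param k k-mer length (<= 31).
#' @param min_hit_fraction Removal threshold on the hit fraction.
#' @return A list with `kept` and `removed` read tibbles.
#' @export
deplete_by_reference <- function(reads, reference_sequences, k = 31,
                                 min_hit_fraction = 0.5) {
  assert_reads(reads)
  if (length(reference_sequences) == 0 ||
      all(nchar(reference_sequences) < k)) {
    warning("empty reference: depletion is a no-op")
    return(list(kept = reads, removed = reads[0, ]))
  }
  set <- if (inherits(reference_sequences, "mtx_kmer_set")) {
    reference_sequences
  } else {
    kmer_set(reference_sequences, k)
  }
  frac <- kset_fraction(set$ptr, reads$seq)
  rm <- frac >= min_hit_fraction
  list(kept = reads[!rm, ], removed = reads[rm, ])
}

#' Build a reusable reference k-mer set
#'
#' @param sequences Character vector of reference sequences.
#' @param k k-mer length.
#' @return An `mtx_kmer_set` (external pointer; rebuild after serialization).
#' @export
kmer_set <- function(sequences, k = 31) {
  structure(list(ptr = kset_build(unname(unlist(sequences)), as.integer(k)),
                 k = as.integer(k)),
            class = "mtx_kmer_set")
}

#' @export
print.mtx_kmer_set <- function(x, ...) {
  cat("<mtx_kmer_set> k =", x$k, "|", format(kset_size(x$ptr), big.mark = ","),
      "distinct k-mers\n")
  invisible(x)
}

#' Full pre-processing: adapter + quality trimming, then host, virus and
#' rRNA depletion
#'
#' Stages run in a fixed order (adapter, quality, host, virus, rRNA) so
#' per-stage counts are well defined. Returns the surviving reads together
#' with a per-stage accounting report.
#'
#' @param reads Read tibble.
#' @param reference `mtx_reference` providing `host`, `virus` and `rrna`
#'   sequence sets.
#' @param k k-mer length for depletion.
#' @param min_hit_fraction Depletion threshold.
#' @param window,min_mean_q Quality-trimming parameters.
#' @param adapter Optional adapter string.
#' @return A list with `reads` (surviving read tibble) and `report`, a
#'   one-row tibble with columns `input_reads`, `quality_pass`,
#'   `removed_host`, `removed_virus`, `removed_rrna`, `surviving`.
#' @examples
#' fix <- build_toy_reference(3, 3, genome_len = 2000, genes_per_species = 3,
#'                            seed = 1)
#' rs <- simulate_sample(fix$reference, fix$community, 0.5, 400, seed = 2)
#' pp <- preprocess(rs, fix$reference)
#' pp$report
#' @export
preprocess <- function(reads, reference, k = 31, min_hit_fraction = 0.5,
                       window = 4, min_mean_q = 20, adapter = NULL) {
  assert_reads(reads)
  input <- nrow(reads)
  reads <- trim_adapters(reads, adapter)
  reads <- quality_trim(reads, window, min_mean_q)
  quality_pass <- nrow(reads)
  st_host <- deplete_by_reference(reads, reference$host, k, min_hit_fraction)
  st_virus <- deplete_by_reference(st_host$kept, reference$virus, k,
                                   min_hit_fraction)
  st_rrna <- deplete_by_reference(st_virus$kept, reference$rrna, k,
                                  min_hit_fraction)
  report <- tibble(
    input_reads = input,
    quality_pass = quality_pass,
    removed_host = nrow(st_host$removed),
    removed_virus = nrow(st_virus$removed),
    removed_rrna = nrow(st_rrna$removed),
    surviving = nrow(st_rrna$kept)
  )
  stopifnot(report$surviving ==
              report$quality_pass - report$removed_host -
              report$removed_virus - report$removed_rrna)
  list(reads = st_rrna$kept, report = report)
}
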