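#' Simulate a cell-ratio host-microbiome sample
#'
#' Emulates a synthetic sample mixed at the *cell* level: a community of
#' bacterial cells spiked with host cells at `host_fraction`. Because the
#' library sequences transcripts, not cells, read shares follow per-cell
#' transcript weights: the expected host read share among non-nuisance reads
#' is
#' \deqn{\frac{f h}{f h + (1-f)\sum_s c_s a_s}}
#' where `f` is the host cell fraction, `h` the host transcripts-per-cell
#' weight (`host_weight`, default much larger than the bacterial weight of
#' 1), and `c_s`, `a_s` the cell fraction and activity of species `s`. A
#' species with activity 0 contributes no reads for any seed. Small rRNA and
#' viral nuisance fractions are taken off the top of the depth.
#'
#' Reads are uniform substrings of the source transcript pools (length-
#' weighted gene choice), carry independent per-base substitution errors at
#' `error_rate`, and get Phred qualities in which a `low_q_tail_frac` share
#' of reads has a sub-Q20 3' tail, to exercise quality trimming.
#'
#' @param reference `mtx_reference` from [build_toy_reference()].
#' @param community Community tibble (cell fractions and activities).
#' @param host_fraction Host *cell* fraction in `[0, 1]`.
#' @param depth Total number of reads.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution probability.
#' @param host_weight Host transcripts-per-cell weight `h`.
#' @param rrna_frac,virus_frac Expected nuisance read fractions.
#' @param low_q_tail_frac Fraction of reads given a low-quality 3' tail.
#' @param id_prefix Prefix for read ids.
#' @return A read tibble with columns `read_id`, `seq`, `qual` (Phred+33)
#'   and the hidden ground-truth column `truth` (one of `species:<id>`,
#'   `host`, `rrna`, `virus`). `truth` is for evaluation only and must not
#'   be shown to profilers.
#' @examples
#' fix <- build_toy_reference(4, 3, genome_len = 2000, genes_per_species = 3,
#'                            seed = 1)
#' rs <- simulate_sample(fix$reference, fix$community, host_fraction = 0.9,
#'                       depth = 500, seed = 7)
#' table(sub(":.*", "", rs$truth))
#' @export
simulate_sample <- function(reference, community, host_fraction, depth, seed,
                            read_len = 100, error_rate = 0.005,
                            host_weight = 20, rrna_frac = 0.02,
                            virus_frac = 0.005, low_q_tail_frac = 0.1,
                            id_prefix = "r") {
  validate_community(community)
  if (host_fraction < 0 || host_fraction > 1) {
    stop("host_fraction must be in [0, 1]", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  w_host <- host_fraction * host_weight
  w_sp <- (1 - host_fraction) * community$cell_fraction * community$activity
  if (w_host + sum(w_sp) <= 0) {
    stop("empty library: host_fraction is 0 and all activities are 0",
         call. = FALSE)
  }
  withr::local_seed(seed)
  p_main <- (1 - rrna_frac - virus_frac) *
    c(w_host, w_sp) / (w_host + sum(w_sp))
  probs <- c(rrna_frac, virus_frac, p_main)
  labels <- c("rrna", "virus", "host", paste0("species:", community$species_id))
  counts <- as.integer(rmultinom(1, depth, probs))

  pools <- c(list(rrna = reference$rrna, virus = reference$virus,
                  host = reference$host),
             split(reference$pangenome$seq, reference$pangenome$species_id)[
               community$species_id])
  pieces <- purrr::map(seq_along(labels), function(i) {
    n <- counts[i]
    if (n == 0) return(NULL)
    pool <- pools[[i]]
    tibble(seq = draw_substrings(pool, n, read_len), truth = labels[i])
  })
  reads <- dplyr::bind_rows(pieces)
  reads <- reads[sample.int(nrow(reads)), ]
  reads$seq <- cpp_add_errors(reads$seq, error_rate)
  tibble(
    read_id = paste0(id_prefix, seq_len(nrow(reads))),
    seq = reads$seq,
    qual = cpp_sim_quals(nchar(reads$seq), low_q_tail_frac, 34, 3),
    truth = reads$truth
  )
}

# n uniform substrings of length read_len from a pool of sequences, pool
# members weighted by their number of valid start positions
draw_substrings <- function(pool, n, read_len) {
  pool <- unname(unlist(pool))
  npos <- nchar(pool) - read_len + 1L
  keep <- npos > 0L
  if (!any(keep)) stop("no pool sequence is as long as read_len", call. = FALSE)
  pool <- pool[keep]
  npos <- npos[keep]
  src <- sample.int(length(pool), n, replace = TRUE, prob = npos)
  start <- floor(stats::runif(n) * npos[src]) + 1L
  substring(pool[src], start, start + read_len - 1L)
}

#' Mix host and microbial read pools at an exact read fraction
#'
#' Emulates the read-level simulated-dataset design: reads are sampled
#' without replacement from a microbial pool and a host pool and combined so
#' that the output contains exactly `round(host_fraction * depth)` host reads
#' and the remainder microbial reads, at a fixed total depth.
#'
#' @param microbial_pool,host_pool Read tibbles to draw from.
#' @param host_fraction Host *read* fraction in `[0, 1]`.
#' @param depth Total number of reads in the output.
#' @param seed Integer seed.
#' @return A read tibble of exactly `depth` rows (order shuffled).
#' @export
mix_reads <- function(microbial_pool, host_pool, host_fraction, depth, seed) {
  if (host_fraction < 0 || host_fraction > 1) {
    stop("host_fraction must be in [0, 1]", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  n_host <- as.integer(round(host_fraction * depth))
  n_mic <- as.integer(depth) - n_host
  if (n_host > nrow(host_pool)) {
    stop("host pool exhausted: need ", n_host, " reads, pool has ",
         nrow(host_pool), call. = FALSE)
  }
  if (n_mic > nrow(microbial_pool)) {
    stop("microbial pool exhausted: need ", n_mic, " reads, pool has ",
         nrow(microbial_pool), call. = FALSE)
  }
  withr::local_seed(seed)
  out <- dplyr::bind_rows(
    host_pool[sample.int(nrow(host_pool), n_host), ],
    microbial_pool[sample.int(nrow(microbial_pool), n_mic), ]
  )
  out[sample.int(nrow(out)), ]
}

#' Inject cross-sample reagent contaminants
#'
#' Adds contaminant reads to each sample under a constant-contaminant-mass
#' model: the expected number of contaminant reads per taxon and sample is
#' `load / concentration`, so contaminant *frequency* is inversely related
#' to sample concentration -- the signature that frequency-based
#' decontamination detects. Counts are Poisson-distributed.
#'
#' @param samples Named list of read tibbles (one per sample).
#' @param reference `mtx_reference` built with `n_contaminants > 0`.
#' @param concentrations Named numeric vector of sample concentrations
#'   (names matching `samples`), all > 0.
#' @param load Expected contaminant reads per taxon at concentration 1.
#' @param seed Integer seed.
#' @param contaminant_ids Which contaminant taxa to inject (default: all in
#'   the reference). Empty vector returns the samples unchanged.
#' @param read_len,error_rate Read simulation parameters.
#' @return The list of read tibbles with contaminant reads appended, truth
#'   labelled `contaminant:<taxon_id>`.
#' @export
inject_contaminants <- function(samples, reference, concentrations,
                                load = 50, seed = 1,
                                contaminant_ids = reference$contaminant_ids,
                                read_len = 100, error_rate = 0.005) {
  if (length(contaminant_ids) == 0) return(samples)
  if (is.null(names(samples)) || !all(names(samples) %in% names(concentrations))) {
    stop("samples and concentrations must share names", call. = FALSE)
  }
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  withr::local_seed(seed)
  purrr::imap(samples, function(reads, sname) {
    conc <- concentrations[[sname]]
    extra <- purrr::map(contaminant_ids, function(tx) {
      n <- rpois(1, load / conc)
      if (n == 0) return(NULL)
      seqs <- cpp_add_errors(
        draw_substrings(reference$species_genomes[[tx]], n, read_len),
        error_rate)
      tibble(
        read_id = paste0(sname, "_ctm_", tx, "_", seq_len(n)),
        seq = seqs,
        qual = cpp_sim_quals(nchar(seqs), 0, 34, 3),
        truth = paste0("contaminant:", tx)
      )
    })
    dplyr::bind_rows(c(list(reads), extra))
  })
}

#' Frequency table of truth labels across samples
#'
#' Convenience for decontamination tests: per-sample relative frequency of
#' each species-level truth label (species and contaminant reads only). Uses
#' only the hidden labels, never the sequences.
#'
#' @param samples Named list of read tibbles.
#' @return Tibble with `sample_id`, `taxon_id`, `frequency`.
#' @export
truth_frequencies <- function(samples) {
  purrr::imap_dfr(samples, function(reads, sname) {
    lab <- reads$truth
    tx <- dplyr::case_when(
      startsWith(lab, "species:") ~ sub("^species:", "", lab),
      startsWith(lab, "contaminant:") ~ sub("^contaminant:", "", lab),
      TRUE ~ NA_character_
    )
    tx <- tx[!is.na(tx)]
    if (length(tx) == 0) return(NULL)
    tibble(sample_id = sname, taxon_id = names(table(tx)),
           frequency = as.numeric(table(tx) / length(tx)))
  })
}
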