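#' Build a toy reference universe for simulation and classification
#'
#' Generates the full closed universe all reads are simulated from and
#' classified against: per-species genomes (i.i.d. random sequence, plus a
#' short identical block shared between congeneric species so that some
#' k-mers resolve only to genus level), per-species transcript pools
#' ("pangenome" genes, substrings of the genome, each carrying a gene-family
#' id and a stored peptide translation), host transcripts, rRNA and viral
#' nuisance sequences, and optional low-level contaminant species that live
#' in the classifier database but not in the community.
#'
#' @param n_species Number of community species (default 20, the mock).
#' @param n_genera Number of genera (default 18; two genera then hold a
#'   congeneric pair).
#' @param genome_len Genome length per species in bp; must be at least
#'   10x `read_len`.
#' @param genes_per_species Number of transcript-pool genes per species.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param read_len Read length the reference must support (precondition
#'   checks only).
#' @param shared_block_len Length of the identical block copied between
#'   congeneric species (default `2 * 31` bp).
#' @param gene_len_range Min/max gene length in bp.
#' @param n_host_transcripts,host_transcript_len Host transcriptome stand-in.
#' @param n_rrna,rrna_len rRNA reference stand-in.
#' @param n_virus,virus_len Viral reference stand-in.
#' @param n_contaminants Number of contaminant species to add to the
#'   reference (and taxonomy) outside the community.
#' @return A list with elements `taxonomy` (tibble), `reference` (an
#'   `mtx_reference` list) and `community` (tibble with `species_id`,
#'   `genus_id`, `cell_fraction`, `activity`). Cell fractions are even and
#'   activities all 1; see [set_activity()].
#' @examples
#' fix <- build_toy_reference(n_species = 4, n_genera = 3, genome_len = 2000,
#'                            genes_per_species = 4, seed = 1)
#' names(fix)
#' @export
build_toy_reference <- function(n_species = 20, n_genera = 18,
                                genome_len = 20000, genes_per_species = 12,
                                seed = 1, read_len = 100,
                                shared_block_len = 62,
                                gene_len_range = c(600, 1200),
                                n_host_transcripts = 120,
                                host_transcript_len = 1200,
                                n_rrna = 6, rrna_len = 1500,
                                n_virus = 4, virus_len = 6000,
                                n_contaminants = 0) {
  if (n_genera < 1 || n_genera > n_species) {
    stop("need 1 <= n_genera <= n_species", call. = FALSE)
  }
  if (genome_len < 10 * read_len) {
    stop("genome_len must be >= 10x read_len", call. = FALSE)
  }
  slot <- genome_len %/% genes_per_species
  if (slot < max(gene_len_range)) {
    stop("genome too short for ", genes_per_species, " genes of up to ",
         max(gene_len_range), " bp", call. = FALSE)
  }
  contaminant_ids <- if (n_contaminants > 0) paste0("C", seq_len(n_contaminants)) else character()
  taxonomy <- toy_taxonomy(n_species, n_genera, contaminant_ids = contaminant_ids)

  withr::local_seed(seed)
  sp_ids <- paste0("S", seq_len(n_species))
  genomes <- setNames(vapply(sp_ids, function(i) random_dna(genome_len),
                             character(1)), sp_ids)

  # identical block between each congeneric pair, placed inside a gene slot
  # of both species so the block is transcribed (reads can cover it)
  genus_of <- species_genus_map(n_species, n_genera)
  for (g in unique(genus_of[duplicated(genus_of)])) {
    pair <- sp_ids[genus_of == g]
    src <- genomes[[pair[1]]]
    # block from the interior of the first gene slot of the donor
    at <- sample(seq(10L, min(gene_len_range) - shared_block_len - 10L), 1)
    block <- substr(src, at, at + shared_block_len - 1L)
    for (other in pair[-1]) {
      at2 <- sample(seq(10L, min(gene_len_range) - shared_block_len - 10L), 1)
      substr(genomes[[other]], at2, at2 + shared_block_len - 1L) <- block
    }
  }

  # genes: one per equal-width genome slot, random length, random offset
  pangenome <- purrr::map_dfr(sp_ids, function(sp) {
    lens <- sample(seq(gene_len_range[1], gene_len_range[2]), genes_per_species,
                   replace = TRUE)
    # first gene starts at slot start so a shared block (placed near the slot
    # head) is always inside it
    offs <- c(0L, vapply(lens[-1], function(l) {
      sample.int(slot - l + 1L, 1) - 1L
    }, integer(1)))
    start <- (seq_len(genes_per_species) - 1L) * slot + offs + 1L
    tibble(
      species_id = sp,
      gene_id = paste0(sp, "_g", seq_len(genes_per_species)),
      gene_family_id = paste0("UF_", sp, "_g", seq_len(genes_per_species)),
      start = start,
      length = lens,
      seq = substring(genomes[[sp]], start, start + lens - 1L)
    )
  })

  protein_db <- pangenome |>
    dplyr::mutate(peptide = translate_frame1(.data$seq)) |>
    dplyr::select("gene_family_id", "peptide")

  host <- setNames(vapply(seq_len(n_host_transcripts),
                          function(i) random_dna(host_transcript_len),
                          character(1)),
                   paste0("host_tx", seq_len(n_host_transcripts)))
  rrna <- setNames(vapply(seq_len(n_rrna), function(i) random_dna(rrna_len),
                          character(1)), paste0("rrna", seq_len(n_rrna)))
  virus <- setNames(vapply(seq_len(n_virus), function(i) random_dna(virus_len),
                           character(1)), paste0("virus", seq_len(n_virus)))

  contam_genomes <- setNames(
    vapply(contaminant_ids, function(i) random_dna(genome_len), character(1)),
    contaminant_ids)

  reference <- structure(list(
    taxonomy = taxonomy,
    species_genomes = c(genomes, contam_genomes),
    pangenome = pangenome,
    protein_db = protein_db,
    host = host,
    rrna = rrna,
    virus = virus,
    contaminant_ids = contaminant_ids,
    genome_len = genome_len
  ), class = "mtx_reference")

  community <- tibble(
    species_id = sp_ids,
    genus_id = genus_of,
    cell_fraction = rep(1 / n_species, n_species),
    activity = rep(1, n_species)
  )
  list(taxonomy = taxonomy, reference = reference, community = community)
}

# frame-1 translation, trimmed to a codon multiple; stops kept as '*'
translate_frame1 <- function(seqs) {
  trimmed <- substr(seqs, 1L, (nchar(seqs) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                     no.init.codon = TRUE))
}

#' @export
print.mtx_reference <- function(x, ...) {
  cat("<mtx_reference>\n")
  cat("  species genomes :", length(x$species_genomes),
      sprintf("(%d community + %d contaminant)",
              length(x$species_genomes) - length(x$contaminant_ids),
              length(x$contaminant_ids)), "\n")
  cat("  pangenome genes :", nrow(x$pangenome), "\n")
  cat("  host transcripts:", length(x$host), "\n")
  cat("  rRNA / viral    :", length(x$rrna), "/", length(x$virus), "\n")
  invisible(x)
}

#' Set per-species transcriptional activity
#'
#' Activity is the transcripts-per-cell weight of a species; 0 makes the
#' species transcriptionally silent (it then contributes no reads for any
#' seed, emulating a community member whose transcripts are absent from the
#' library).
#'
#' @param community Community tibble from [build_toy_reference()].
#' @param species_id Species to modify.
#' @param activity New non-negative activity value(s).
#' @return The community tibble with updated activities.
#' @export
set_activity <- function(community, species_id, activity) {
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  i <- match(species_id, community$species_id)
  if (anyNA(i)) stop("unknown species: ",
                     paste(species_id[is.na(i)], collapse = ", "), call. = FALSE)
  community$activity[i] <- activity
  community
}

#' Validate a community specification
#'
#' @param community Community tibble (`species_id`, `genus_id`,
#'   `cell_fraction`, `activity`).
#' @return The community invisibly, or an error if cell fractions do not sum
#'   to 1 (tolerance 1e-9) or activities are negative.
#' @export
validate_community <- function(community) {
  if (abs(sum(community$cell_fraction) - 1) > 1e-9) {
    stop("cell fractions must sum to 1", call. = FALSE)
  }
  if (any(community$activity < 0)) stop("activity must be >= 0", call. = FALSE)
  invisible(community)
}
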