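#' Build a k-mer LCA index over the reference genomes
#'
#' Every canonical k-mer (lexicographic minimum of the k-mer and its reverse
#' complement) of every species genome is stored with the lowest common
#' ancestor of all species whose genomes contain it: k-mers unique to one
#' species map to that species, k-mers shared by congeneric species map to
#' their genus, and so on up the tree. Per-species distinct-k-mer totals are
#' kept for the reestimation fallback.
#'
#' @param reference `mtx_reference` (community plus any contaminant genomes).
#' @param taxonomy Taxonomy tibble; defaults to the one in `reference`.
#' @param k k-mer length; odd values in 15..31 are recommended.
#' @return A `kmer_index` holding an external-pointer hash map, `k`, the
#'   taxonomy index and a `species_kmer_totals` tibble. The pointer does not
#'   survive serialization; rebuild the index per session.
#' @export
build_kmer_index <- function(reference, taxonomy = reference$taxonomy, k = 31) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]", call. = FALSE)
  if (k %% 2 == 0 || k < 15) {
    warning("odd k in 15..31 is recommended (canonical-form ties, specificity)")
  }
  genomes <- reference$species_genomes
  if (anyDuplicated(names(genomes))) {
    stop("duplicate species ids in reference", call. = FALSE)
  }
  if (!all(names(genomes) %in% taxonomy$taxon_id)) {
    stop("genome species missing from taxonomy", call. = FALSE)
  }
  idx <- taxonomy_index(taxonomy)
  taxon <- match(names(genomes), idx$ids)
  ptr <- kidx_build(unname(genomes), as.integer(taxon), idx$parent, idx$depth,
                    as.integer(k))
  totals <- tibble(
    taxon_id = names(genomes),
    n_kmers = vapply(genomes, function(g) kset_size(kset_build(g, as.integer(k))),
                     numeric(1))
  )
  structure(list(ptr = ptr, k = as.integer(k), taxonomy = taxonomy,
                 index = idx, species_kmer_totals = totals),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "|",
      format(kidx_size(x$ptr), big.mark = ","), "k-mers |",
      nrow(x$species_kmer_totals), "species\n")
  invisible(x)
}

#' @export
glance.kmer_index <- function(x, ...) {
  tibble(k = x$k, n_kmers = kidx_size(x$ptr),
         n_species = nrow(x$species_kmer_totals))
}

#' Classify reads by k-mer LCA with a confidence threshold
#'
#' For each read, all valid k-mers are looked up in the index and their hit
#' taxa collected. The candidate is the leaf-ward taxon maximizing the
#' summed hits along its root-to-node path (ties: deepest node, then lowest
#' taxon id). The confidence of a taxon is the fraction of the read's valid
#' k-mers hitting any taxon in its rooted clade; if the candidate's
#' confidence is below `confidence`, the assignment ascends toward the root,
#' re-testing the threshold at each ancestor, and the read is unclassified
#' if even the root fails. Reads with no hits (or shorter than `k`) are
#' unclassified with confidence 0.
#'
#' @param reads Read tibble.
#' @param index `kmer_index` from [build_kmer_index()].
#' @param confidence Confidence threshold in `[0, 1]`; at 0 any read with at
#'   least one hit is classified.
#' @return Tibble with `read_id`, `taxon_id` (`NA` if unclassified), `rank`
#'   and `confidence`.
#' @export
classify_reads <- function(reads, index, confidence = 0) {
  assert_reads(reads)
  if (confidence < 0 || confidence > 1) {
    stop("confidence must be in [0, 1]", call. = FALSE)
  }
  res <- kidx_classify(index$ptr, reads$seq, index$index$parent,
                       index$index$depth, confidence)
  taxon <- ifelse(res$taxon == 0L, NA_character_, index$index$ids[res$taxon])
  tibble(
    read_id = reads$read_id,
    taxon_id = taxon,
    rank = ifelse(is.na(taxon), NA_character_,
                  index$taxonomy$rank[match(taxon, index$taxonomy$taxon_id)]),
    confidence = res$confidence
  )
}

#' Aggregate read classifications into a (possibly mixed-rank) profile
#'
#' @param classified Output of [classify_reads()].
#' @param taxonomy Taxonomy tibble.
#' @return A `tax_profile` with one entry per assigned taxon (any rank) and
#'   the unclassified read count recorded.
#' @export
profile_from_classification <- function(classified, taxonomy) {
  hit <- classified[!is.na(classified$taxon_id), ]
  counts <- hit |>
    dplyr::count(.data$taxon_id, name = "read_count")
  rank <- if (nrow(counts) == 0 ||
              !all(taxonomy$rank[match(counts$taxon_id, taxonomy$taxon_id)] ==
                   "species")) "mixed" else "species"
  tax_profile(counts, taxonomy, rank,
              unclassified = sum(is.na(classified$taxon_id)))
}

#' Reestimate species-level counts from a mixed-rank profile
#'
#' Reads assigned to internal taxonomy nodes (genus and above) are
#' redistributed to the descendant species of each node, proportionally to
#' those species' direct species-level counts; where all descendant species
#' of a node have zero direct counts, the redistribution falls back to the
#' species' distinct-k-mer totals from the index (equal weights if neither
#' is available). Species counts are then renormalized to relative
#' abundances. Total read count is conserved exactly.
#'
#' @param profile A `tax_profile` with counts at any rank.
#' @param taxonomy Taxonomy tibble.
#' @param kmer_totals Either a `kmer_index` or a tibble with `taxon_id` and
#'   `n_kmers`; optional.
#' @return A species-rank `tax_profile` (fractional counts possible).
#' @export
reestimate_species <- function(profile, taxonomy, kmer_totals = NULL) {
  if (inherits(kmer_totals, "kmer_index")) {
    kmer_totals <- kmer_totals$species_kmer_totals
  }
  rk <- taxonomy$rank[match(profile$taxon_id, taxonomy$taxon_id)]
  if (anyNA(rk)) stop("profile contains taxa missing from the taxonomy",
                      call. = FALSE)
  direct <- setNames(profile$read_count, profile$taxon_id)[rk == "species"]
  species_counts <- setNames(rep(0, sum(taxonomy$rank == "species")),
                             taxonomy$taxon_id[taxonomy$rank == "species"])
  species_counts[names(direct)] <- direct
  internal <- profile[rk != "species", ]
  for (i in seq_len(nrow(internal))) {
    node <- internal$taxon_id[i]
    cnt <- internal$read_count[i]
    desc <- taxonomy_species_under(taxonomy, node)
    w <- setNames(rep(0, length(desc)), desc)
    hit <- intersect(desc, names(direct))
    w[hit] <- direct[hit]
    if (sum(w) == 0) {
      if (!is.null(kmer_totals)) {
        w[] <- kmer_totals$n_kmers[match(desc, kmer_totals$taxon_id)]
        w[is.na(w)] <- 0
      }
      if (sum(w) == 0) {
        warning("no direct counts or k-mer totals under ", node,
                "; distributing equally")
        w[] <- 1
      }
    }
    species_counts[desc] <- species_counts[desc] + cnt * w / sum(w)
  }
  keep <- species_counts > 0
  new_tax_profile(
    tibble(taxon_id = names(species_counts)[keep], rank = "species",
           read_count = unname(species_counts[keep])),
    "species", unclassified_count(profile))
}

#' One-call k-mer taxonomic profiling
#'
#' [classify_reads()] then [profile_from_classification()] then
#' [reestimate_species()].
#'
#' @inheritParams classify_reads
#' @return A species-rank `tax_profile`.
#' @export
profile_kmer <- function(reads, index, confidence = 0) {
  cls <- classify_reads(reads, index, confidence)
  prof <- profile_from_classification(cls, index$taxonomy)
  reestimate_species(prof, index$taxonomy, index)
}
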