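#' Taxonomic prescreen for functional profiling
#'
#' Species whose relative abundance in the (decontaminated, species-rank)
#' profile is at least `threshold`, ordered by descending abundance then
#' taxon id. The returned list defines the sample-specific pangenome subset
#' searched at the nucleotide tier.
#'
#' @param profile A species-rank `tax_profile`.
#' @param threshold Minimum relative abundance (default 0.001).
#' @return Character vector of species ids (possibly empty).
#' @export
prescreen <- function(profile, threshold = 0.001) {
  if (profile_rank(profile) != "species") {
    stop("prescreen needs a species-rank profile", call. = FALSE)
  }
  keep <- profile[profile$rel_abundance >= threshold &
                    profile$rel_abundance > 0, ]
  keep <- keep[order(-keep$rel_abundance, keep$taxon_id), ]
  keep$taxon_id
}

#' Restrict the pangenome to a species subset
#'
#' @param reference `mtx_reference`.
#' @param species Character vector of species ids (e.g. from [prescreen()]).
#' @return Pangenome tibble restricted to those species.
#' @export
pangenome_subset <- function(reference, species) {
  reference$pangenome[reference$pangenome$species_id %in% species, ]
}

#' Nucleotide-tier search against a sample-specific pangenome
#'
#' Each read is assigned to the gene sharing the most k-mers with it,
#' subject to a minimum shared fraction (ties: longest gene, then gene id).
#' After assignment, genes whose covered fraction of positions (union of
#' assigned-read intervals) is below `subject_coverage_threshold` percent
#' are dropped and their reads rerouted to unmapped; surviving counts are
#' stratified by the gene's species.
#'
#' @param reads Read tibble.
#' @param pangenome Pangenome tibble (a [pangenome_subset()]).
#' @param k k-mer length.
#' @param min_hit_fraction Minimum shared-k-mer fraction for assignment.
#' @param subject_coverage_threshold Percent of gene positions that must be
#'   covered (default 25).
#' @return A list with `counts` (tibble `gene_id`, `gene_family_id`,
#'   `species_id`, `length`, `reads`) and `unmapped` (read tibble).
#' @export
nucleotide_search <- function(reads, pangenome, k = 31, min_hit_fraction = 0.5,
                              subject_coverage_threshold = 25) {
  assert_reads(reads)
  if (nrow(pangenome) == 0) {
    return(list(counts = tibble(gene_id = character(),
                                gene_family_id = character(),
                                species_id = character(),
                                length = integer(), reads = integer()),
                unmapped = reads))
  }
  km <- kmap_build(pangenome$seq, as.integer(k))
  tie_rank <- order(order(-pangenome$length, pangenome$gene_id))
  asg <- kmap_assign(km, reads$seq, nrow(pangenome), min_hit_fraction,
                     as.integer(tie_rank))
  assigned <- asg$target > 0L
  hits <- tibble(
    row = which(assigned),
    gene = asg$target[assigned],
    start = asg$start[assigned],
    read_len = nchar(reads$seq[assigned])
  )
  # subject coverage: union of assigned-read intervals per gene
  keep_gene <- rep(TRUE, nrow(pangenome))
  for (g in unique(hits$gene)) {
    h <- hits[hits$gene == g, ]
    glen <- pangenome$length[g]
    ir <- IRanges::IRanges(start = pmin(h$start, glen),
                           end = pmin(h$start + h$read_len - 1L, glen))
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    if (100 * covered / glen < subject_coverage_threshold) keep_gene[g] <- FALSE
  }
  hits <- hits[keep_gene[hits$gene], ]
  counts <- hits |>
    dplyr::count(.data$gene, name = "reads") |>
    dplyr::mutate(gene_id = pangenome$gene_id[.data$gene],
                  gene_family_id = pangenome$gene_family_id[.data$gene],
                  species_id = pangenome$species_id[.data$gene],
                  length = pangenome$length[.data$gene]) |>
    dplyr::select("gene_id", "gene_family_id", "species_id", "length", "reads")
  unmapped <- reads[setdiff(seq_len(nrow(reads)), hits$row), ]
  list(counts = counts, unmapped = unmapped)
}

#' Translated-tier search against the protein database
#'
#' Each unmapped read is translated in all six frames, split at stop codons,
#' and assigned to the gene family sharing the most peptide k-mers (at least
#' one); its contributor is reported as `"unclassified"` since the tier is
#' community-level, not species-stratified. Reads sharing no peptide k-mer
#' with any family stay unmapped.
#'
#' @param unmapped Read tibble (nucleotide-tier leftovers).
#' @param protein_db Tibble with `gene_family_id`, `peptide`.
#' @param peptide_k Peptide k-mer length (default 7, large enough
#'   that chance matches are negligible; must satisfy
#'   `peptide_k <= floor(read_len / 3)`).
#' @return A list with `counts` (tibble `gene_family_id`, `reads`) and
#'   `unmapped_count`.
#' @export
translated_search <- function(unmapped, protein_db, peptide_k = 7) {
  assert_reads(unmapped)
  if (nrow(unmapped) == 0) {
    return(list(counts = tibble(gene_family_id = character(),
                                reads = integer()),
                unmapped_count = 0L))
  }
  if (peptide_k > floor(min(nchar(unmapped$seq)) / 3)) {
    stop("peptide_k must be <= floor(read_len / 3)", call. = FALSE)
  }
  fam_map <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(protein_db))) {
    for (pep in strsplit(protein_db$peptide[i], "*", fixed = TRUE)[[1]]) {
      for (kk in peptide_kmers(pep, peptide_k)) {
        cur <- fam_map[[kk]]
        fam_map[[kk]] <- unique(c(cur, protein_db$gene_family_id[i]))
      }
    }
  }
  assigned <- vapply(unmapped$seq, function(s) {
    votes <- character()
    for (pep in six_frame_peptides(s)) {
      for (kk in peptide_kmers(pep, peptide_k)) {
        fams <- fam_map[[kk]]
        if (!is.null(fams)) votes <- c(votes, fams)
      }
    }
    if (length(votes) == 0) return(NA_character_)
    tab <- sort(table(votes), decreasing = TRUE)
    names(tab)[tab == tab[1]][1]  # ties: lowest family id
  }, character(1), USE.NAMES = FALSE)
  counts <- tibble(gene_family_id = assigned[!is.na(assigned)]) |>
    dplyr::count(.data$gene_family_id, name = "reads")
  list(counts = counts, unmapped_count = sum(is.na(assigned)))
}

# stop-codon-split peptides of all 6 reading frames
six_frame_peptides <- function(seq) {
  rc <- revcomp(seq)
  frames <- c(vapply(1:3, function(f) substring(seq, f), character(1)),
              vapply(1:3, function(f) substring(rc, f), character(1)))
  peps <- translate_frame1(frames)
  unlist(strsplit(peps, "*", fixed = TRUE), use.names = FALSE)
}

peptide_kmers <- function(pep, k) {
  n <- nchar(pep)
  if (n < k) return(character())
  unique(substring(pep, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Quantify a tiered functional search as RPK and CPM
#'
#' RPK of a row is `reads / (length / 1000)`; the translated tier uses the
#' family's representative length (median source-gene length). CPM is the
#' RPK sum-normalized to one million across all rows. Per-tier CPM totals
#' and the final unmapped read count are recorded as attributes.
#'
#' @param nuc Output of [nucleotide_search()].
#' @param trans Output of [translated_search()], or `NULL`.
#' @param reference `mtx_reference` (for family representative lengths).
#' @return A `functional_profile` tibble with columns `gene_family_id`,
#'   `contributor`, `tier`, `reads`, `rpk`, `cpm`, and attributes
#'   `tier_totals` (named CPM) and `unmapped_count`.
#' @export
quantify <- function(nuc, trans = NULL, reference = NULL) {
  nrow_tbl <- nuc$counts |>
    dplyr::mutate(rpk = .data$reads / (.data$length / 1000)) |>
    dplyr::group_by(.data$gene_family_id, contributor = .data$species_id) |>
    dplyr::summarise(reads = sum(.data$reads), rpk = sum(.data$rpk),
                     .groups = "drop") |>
    dplyr::mutate(tier = "nucleotide")
  trans_tbl <- NULL
  unmapped <- 0L
  if (!is.null(trans)) {
    unmapped <- trans$unmapped_count
    if (nrow(trans$counts) > 0) {
      fam_len <- reference$pangenome |>
        dplyr::group_by(.data$gene_family_id) |>
        dplyr::summarise(rep_len = stats::median(.data$length), .groups = "drop")
      trans_tbl <- trans$counts |>
        dplyr::left_join(fam_len, by = "gene_family_id") |>
        dplyr::mutate(
          rep_len = ifelse(is.na(.data$rep_len), 1000, .data$rep_len),
          rpk = .data$reads / (.data$rep_len / 1000),
          contributor = "unclassified", tier = "translated") |>
        dplyr::select("gene_family_id", "contributor", "reads", "rpk", "tier")
    }
  }
  out <- dplyr::bind_rows(nrow_tbl, trans_tbl)
  total_rpk <- sum(out$rpk)
  if (nrow(out) > 0 && total_rpk == 0) warning("total RPK is zero")
  out$cpm <- if (total_rpk > 0) out$rpk * 1e6 / total_rpk else rep(0, nrow(out))
  tier_totals <- vapply(c("nucleotide", "translated"), function(t) {
    sum(out$cpm[out$tier == t])
  }, numeric(1))
  structure(out[, c("gene_family_id", "contributor", "tier", "reads",
                    "rpk", "cpm")],
            class = c("functional_profile", class(tibble())),
            tier_totals = tier_totals,
            unmapped_count = as.integer(unmapped))
}

#' @export
print.functional_profile <- function(x, ...) {
  tt <- attr(x, "tier_totals")
  cat(sprintf(
    "<functional_profile> %d rows | CPM nucleotide %.0f / translated %.0f | %d unmapped reads\n",
    nrow(x), tt[["nucleotide"]], tt[["translated"]],
    attr(x, "unmapped_count")))
  NextMethod()
}

#' @export
glance.functional_profile <- function(x, ...) {
  tt <- attr(x, "tier_totals")
  tibble(n_gene_families = dplyr::n_distinct(x$gene_family_id),
         cpm_nucleotide = tt[["nucleotide"]],
         cpm_translated = tt[["translated"]],
         unmapped_reads = attr(x, "unmapped_count"))
}

#' Plot per-tier CPM of a functional profile
#'
#' @param object A `functional_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.functional_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(cpm = sum(.data$cpm), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$cpm,
                                   fill = .data$tier)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "search tier", y = "CPM") +
    ggplot2::theme_minimal()
}

#' Full tiered functional profiling
#'
#' [prescreen()] on the taxonomic profile, nucleotide search against the
#' resulting pangenome subset, translated search on the leftovers, then
#' RPK/CPM quantification.
#'
#' @param reads Read tibble (pre-processed).
#' @param profile Decontaminated species-rank `tax_profile`.
#' @param reference `mtx_reference`.
#' @param prescreen_threshold Minimum species abundance (default 0.001).
#' @param k,min_hit_fraction,subject_coverage_threshold,peptide_k Tier
#'   parameters; see the individual functions.
#' @return A `functional_profile`.
#' @export
run_functional_profiling <- function(reads, profile, reference,
                                     prescreen_threshold = 0.001, k = 31,
                                     min_hit_fraction = 0.5,
                                     subject_coverage_threshold = 25,
                                     peptide_k = 7) {
  species <- prescreen(profile, prescreen_threshold)
  nuc <- nucleotide_search(reads, pangenome_subset(reference, species), k,
                           min_hit_fraction, subject_coverage_threshold)
  trans <- translated_search(nuc$unmapped, reference$protein_db, peptide_k)
  quantify(nuc, trans, reference)
}
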