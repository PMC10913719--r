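#' Build a clade-specific marker database
#'
#' Selects, for each species, `markers_per_species` disjoint windows of
#' length `marker_len` from its transcribed regions (pangenome genes) that
#' are verified unique: a candidate is rejected if it (or its reverse
#' complement) occurs in any other species' genome. Windows overlapping a
#' congeneric shared block therefore never become markers. Selection is
#' deterministic for a fixed seed.
#'
#' @param reference `mtx_reference`.
#' @param marker_len Marker window length (bp), at least the read length for
#'   containment-based hits to be possible.
#' @param markers_per_species Markers selected per species.
#' @param seed Integer seed.
#' @return A tibble with `species_id`, `marker_id`, `seq`, `length`.
#' @export
build_marker_db <- function(reference, marker_len = 150,
                            markers_per_species = 10, seed = 1) {
  withr::local_seed(seed)
  genomes <- reference$species_genomes
  community_sp <- setdiff(names(genomes), reference$contaminant_ids)
  purrr::map_dfr(community_sp, function(sp) {
    genes <- reference$pangenome[reference$pangenome$species_id == sp, ]
    others <- genomes[setdiff(names(genomes), sp)]
    # disjoint candidate windows tiled across the species' genes
    cand <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes$seq[i]
      n <- nchar(g) %/% marker_len
      if (n == 0) return(NULL)
      start <- (seq_len(n) - 1L) * marker_len + 1L
      tibble(seq = substring(g, start, start + marker_len - 1L))
    })
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    picked <- character()
    for (w in cand$seq) {
      if (length(picked) == markers_per_species) break
      wrc <- revcomp(w)
      hit <- any(vapply(others, function(gm) {
        grepl(w, gm, fixed = TRUE) || grepl(wrc, gm, fixed = TRUE)
      }, logical(1)))
      if (!hit) picked <- c(picked, w)
    }
    if (length(picked) < markers_per_species) {
      stop("insufficient unique sequence to pick ", markers_per_species,
           " markers for species ", sp, call. = FALSE)
    }
    tibble(species_id = sp,
           marker_id = paste0(sp, "_m", seq_along(picked)),
           seq = picked, length = nchar(picked))
  })
}

#' Marker-based taxonomic profiling
#'
#' A read hits a marker if it shares at least `min_hit_fraction` of its
#' k-mers with that marker (the same containment rule as reference
#' depletion). Marker coverage is `hits * read_len / marker_len`. A species
#' is called present iff at least `g_min` of its markers have one or more
#' hits (a detection threshold in the style of marker-count gating), and a
#' detected species' abundance is the robust average of its marker
#' coverages -- the mean after discarding the top and bottom `stat_q`
#' quantiles (i.e. `floor(stat_q * n)` markers at each end) -- normalized
#' across detected species.
#'
#' @param reads Read tibble.
#' @param marker_db Marker tibble from [build_marker_db()].
#' @param stat_q Trim quantile in `[0, 0.5)`.
#' @param g_min Minimum number of detected markers to call a species (>= 1).
#' @param k k-mer length for containment.
#' @param min_hit_fraction Read-to-marker containment threshold.
#' @return A species-rank `tax_profile` over the detected species.
#' @export
profile_markers <- function(reads, marker_db, stat_q = 0.2, g_min = 3,
                            k = 31, min_hit_fraction = 0.5) {
  assert_reads(reads)
  if (stat_q < 0 || stat_q >= 0.5) stop("stat_q must be in [0, 0.5)", call. = FALSE)
  if (g_min < 1) stop("g_min must be >= 1", call. = FALSE)
  km <- kmap_build(marker_db$seq, as.integer(k))
  hits <- kmap_hit_counts(km, reads$seq, nrow(marker_db), min_hit_fraction)
  read_len <- stats::median(nchar(reads$seq))
  cov <- hits * read_len / marker_db$length
  per_sp <- tibble(species_id = marker_db$species_id, hits = hits, cov = cov) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(n_detected = sum(.data$hits > 0),
                     abundance = robust_mean(.data$cov, stat_q),
                     .groups = "drop") |>
    dplyr::filter(.data$n_detected >= g_min, .data$abundance > 0)
  new_tax_profile(
    tibble(taxon_id = per_sp$species_id, rank = "species",
           read_count = per_sp$abundance),
    "species", 0L)
}

#' Quantile-trimmed robust mean
#'
#' Sorts `x`, drops `floor(q * length(x))` values at each end, and averages
#' the rest.
#'
#' @param x Numeric vector.
#' @param q Trim quantile in `[0, 0.5)`.
#' @return The trimmed mean (scalar).
#' @export
robust_mean <- function(x, q) {
  n <- length(x)
  drop <- floor(q * n)
  if (n - 2 * drop <= 0) return(mean(x))
  mean(sort(x)[(drop + 1):(n - drop)])
}
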