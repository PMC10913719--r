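# Taxonomic profile container: a classed tibble with columns taxon_id, rank,
# read_count, rel_abundance plus attributes `profile_rank` (species, genus or
# mixed) and `unclassified_count`.

new_tax_profile <- function(entries, rank, unclassified = 0L) {
  entries <- as_tibble(entries)
  entries$rel_abundance <-
    if (sum(entries$read_count) > 0) {
      entries$read_count / sum(entries$read_count)
    } else {
      rep(0, nrow(entries))
    }
  structure(entries,
            class = c("tax_profile", class(tibble())),
            profile_rank = rank,
            unclassified_count = unclassified)
}

#' Rank and unclassified count of a taxonomic profile
#'
#' @param profile A `tax_profile`.
#' @return `profile_rank()`: `"species"`, `"genus"` or `"mixed"`;
#'   `unclassified_count()`: number of reads left unclassified upstream.
#' @export
profile_rank <- function(profile) attr(profile, "profile_rank") %||% "mixed"

#' @rdname profile_rank
#' @export
unclassified_count <- function(profile) {
  as.integer(attr(profile, "unclassified_count") %||% 0L)
}

#' Assemble a taxonomic profile from per-taxon read counts
#'
#' @param counts Tibble with `taxon_id` and `read_count` (and optionally
#'   `rank`); relative abundances are computed by renormalizing counts.
#' @param taxonomy Taxonomy tibble used to fill in ranks.
#' @param rank Declared rank of the profile (`"species"`, `"genus"` or
#'   `"mixed"`).
#' @param unclassified Number of unclassified reads to record.
#' @return A `tax_profile` tibble.
#' @export
tax_profile <- function(counts, taxonomy = NULL, rank = "mixed",
                        unclassified = 0L) {
  counts <- as_tibble(counts)
  if (!"rank" %in% names(counts)) {
    counts$rank <- if (!is.null(taxonomy)) {
      taxonomy$rank[match(counts$taxon_id, taxonomy$taxon_id)]
    } else {
      rank
    }
  }
  new_tax_profile(counts[, c("taxon_id", "rank", "read_count")],
                  rank, unclassified)
}

#' @export
print.tax_profile <- function(x, ...) {
  cat(sprintf("<tax_profile> rank = %s | %d taxa | %d unclassified reads\n",
              profile_rank(x), nrow(x), unclassified_count(x)))
  NextMethod()
}

#' @export
tidy.tax_profile <- function(x, ...) {
  as_tibble(x) |> dplyr::arrange(dplyr::desc(.data$rel_abundance))
}

#' @export
glance.tax_profile <- function(x, ...) {
  tibble(rank = profile_rank(x),
         n_taxa = sum(x$rel_abundance > 0),
         total_reads = sum(x$read_count),
         unclassified = unclassified_count(x))
}

#' Plot a taxonomic profile as a relative-abundance bar chart
#'
#' @param object A `tax_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tax_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$taxon_id, -.data$rel_abundance),
    y = .data$rel_abundance)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = paste0("taxon (", profile_rank(object), ")"),
                  y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Write or read a taxonomic profile TSV
#'
#' Two dialects are supported. `"report"` is a rank/count report
#' (`taxon_id`, `rank`, `direct_count`, `clade_count`) in the style of k-mer
#' classifier reports, with an `unclassified` pseudo-row. `"flat"` is a flat
#' relative-abundance table (`lineage`, `rel_abundance`) in the style of
#' marker-profiler output, where `lineage` is the `|`-joined root-to-taxon
#' id path.
#'
#' @param profile A `tax_profile`.
#' @param path Output path.
#' @param taxonomy Taxonomy tibble (needed for clade counts / lineages).
#' @param dialect `"report"` or `"flat"`.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a `tax_profile`.
#' @export
write_profile_tsv <- function(profile, path, taxonomy,
                              dialect = c("report", "flat")) {
  dialect <- match.arg(dialect)
  if (dialect == "report") {
    clade <- vapply(profile$taxon_id, function(id) {
      under <- c(id, taxonomy$taxon_id[vapply(
        taxonomy$taxon_id, function(t) id %in% taxonomy_ancestors(taxonomy, t),
        logical(1))])
      sum(profile$read_count[profile$taxon_id %in% under])
    }, numeric(1))
    out <- tibble(taxon_id = profile$taxon_id, rank = profile$rank,
                  direct_count = profile$read_count, clade_count = clade)
    out <- dplyr::bind_rows(out, tibble(
      taxon_id = "unclassified", rank = "none",
      direct_count = unclassified_count(profile),
      clade_count = unclassified_count(profile)))
    readr::write_tsv(out, path)
  } else {
    lineage <- vapply(profile$taxon_id, function(id) {
      paste(rev(taxonomy_ancestors(taxonomy, id)), collapse = "|")
    }, character(1))
    readr::write_tsv(tibble(lineage = lineage,
                            rel_abundance = profile$rel_abundance), path)
  }
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path, dialect = c("report", "flat")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, col_types = readr::cols())
  if (dialect == "report") {
    uncls <- df$direct_count[df$taxon_id == "unclassified"]
    df <- df[df$taxon_id != "unclassified", ]
    rank <- if (all(df$rank == "species")) "species"
            else if (all(df$rank == "genus")) "genus" else "mixed"
    new_tax_profile(tibble(taxon_id = df$taxon_id, rank = df$rank,
                           read_count = df$direct_count),
                    rank, as.integer(sum(uncls)))
  } else {
    ids <- vapply(strsplit(df$lineage, "|", fixed = TRUE), function(x) {
      x[length(x)]
    }, character(1))
    new_tax_profile(tibble(taxon_id = ids, rank = "species",
                           read_count = df$rel_abundance), "species", 0L)
  }
}
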