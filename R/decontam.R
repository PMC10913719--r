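#' Frequency-mode contaminant scoring
#'
#' For each taxon, compares two regressions of log frequency on log sample
#' concentration over the samples where the taxon is present: the
#' contaminant model (slope fixed at -1, free intercept -- constant
#' contaminant mass diluted by the sample) and the non-contaminant model
#' (slope fixed at 0, free intercept -- frequency independent of
#' concentration). The score is the upper tail probability of the F-type
#' ratio of the two residual sums of squares,
#' `pf(RSS0 / RSS-1, n - 1, n - 1, lower.tail = FALSE)`; small scores mean
#' the inverse-with-concentration (contaminant) model fits far better.
#' Zero frequencies are excluded from the fit (log undefined); taxa with
#' fewer than 4 usable samples get an `NA` score and are retained, flagged
#' `"insufficient data"`.
#'
#' @param freqs Tibble with `sample_id`, `taxon_id`, `frequency` (per-sample
#'   relative abundances, e.g. from [truth_frequencies()] or stacked
#'   profiles).
#' @param concentrations Named numeric vector (or tibble with `sample_id`,
#'   `concentration`) of sample concentrations.
#' @param threshold Score below which a taxon is flagged (default 0.1, the
#'   conventional default for this family of methods).
#' @param protected Taxa never flagged, whatever their score.
#' @return Tibble with `taxon_id`, `score`, `is_contaminant`,
#'   `n_samples_used`, `note`.
#' @export
score_frequency <- function(freqs, concentrations, threshold = 0.1,
                            protected = character()) {
  if (is.data.frame(concentrations)) {
    concentrations <- setNames(concentrations$concentration,
                               concentrations$sample_id)
  }
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  freqs |>
    dplyr::mutate(concentration = concentrations[.data$sample_id]) |>
    dplyr::filter(.data$frequency > 0, !is.na(.data$concentration)) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(
      score = frequency_score_stat(.data$frequency, .data$concentration),
      n_samples_used = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      score = ifelse(.data$n_samples_used < 4, NA_real_, .data$score),
      note = dplyr::case_when(
        .data$n_samples_used < 4 ~ "insufficient data",
        .data$taxon_id %in% protected ~ "protected",
        TRUE ~ ""),
      is_contaminant = !is.na(.data$score) & .data$score < threshold &
        !(.data$taxon_id %in% protected)) |>
    dplyr::select("taxon_id", "score", "is_contaminant", "n_samples_used",
                  "note")
}

# F-type tail score for one taxon
frequency_score_stat <- function(f, conc) {
  lf <- log(f); lc <- log(conc)
  n <- length(f)
  rss_contam <- sum((lf - (mean(lf + lc) - lc))^2)  # slope -1
  rss_null <- sum((lf - mean(lf))^2)                # slope 0
  if (rss_contam == 0 && rss_null == 0) return(NA_real_)
  pf(rss_null / rss_contam, n - 1, n - 1, lower.tail = FALSE)
}

#' Clean a taxonomic profile
#'
#' Removes taxa flagged as contaminants (unless protected), removes taxa
#' whose id or display name matches any of the unclassified-name patterns,
#' and renormalizes the remaining relative abundances to sum to 1. Cleaning
#' is idempotent; protected taxa are never removed for any scores.
#'
#' @param profile A `tax_profile`.
#' @param scores Output of [score_frequency()], or `NULL` to skip
#'   contaminant removal.
#' @param protected Character vector of protected taxon ids.
#' @param unclassified_patterns Regex patterns (case-insensitive) marking
#'   poorly defined taxa to drop.
#' @param taxonomy Optional taxonomy tibble so patterns also match display
#'   names.
#' @return The cleaned, renormalized `tax_profile` (empty with a warning if
#'   everything is removed).
#' @export
clean_profile <- function(profile, scores = NULL, protected = character(),
                          unclassified_patterns = "unclassified",
                          taxonomy = NULL) {
  drop <- rep(FALSE, nrow(profile))
  if (!is.null(scores)) {
    flagged <- scores$taxon_id[scores$is_contaminant]
    drop <- drop | (profile$taxon_id %in% flagged)
  }
  nm <- profile$taxon_id
  if (!is.null(taxonomy)) {
    disp <- taxonomy$name[match(profile$taxon_id, taxonomy$taxon_id)]
    nm <- paste(nm, ifelse(is.na(disp), "", disp))
  }
  for (p in unclassified_patterns) {
    drop <- drop | grepl(p, nm, ignore.case = TRUE)
  }
  drop <- drop & !(profile$taxon_id %in% protected)
  out <- profile[!drop, ]
  if (nrow(out) == 0) warning("all taxa removed: empty profile")
  new_tax_profile(
    tibble(taxon_id = out$taxon_id, rank = out$rank,
           read_count = out$read_count),
    profile_rank(profile), unclassified_count(profile))
}
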