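#' Presence/absence precision, recall and F1 against a known community
#'
#' A taxon counts as detected iff its relative abundance is greater than 0,
#' regardless of its value. `tp` is the number of detected ground-truth
#' taxa, `fp` the detected taxa outside the truth, `fn` the truth taxa not
#' detected. Precision is `tp / (tp + fp)` (0 by convention when nothing is
#' detected), recall `tp / (tp + fn)`, F1 their harmonic mean (0 when both
#' are 0).
#'
#' @param profile A `tax_profile`.
#' @param truth Character vector of expected taxon ids.
#' @param rank Rank the comparison is made at; must equal the profile's
#'   rank (default `"species"`).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' p <- tax_profile(tibble::tibble(taxon_id = c("S1", "S2", "X1"),
#'                                 read_count = c(5, 3, 1)), rank = "species")
#' score_profile(p, c("S1", "S2", "S3"))
#' @export
score_profile <- function(profile, truth, rank = "species") {
  if (length(truth) == 0) stop("truth must be nonempty", call. = FALSE)
  if (profile_rank(profile) != rank) {
    stop("rank mismatch: profile is at rank '", profile_rank(profile),
         "', truth at '", rank, "'", call. = FALSE)
  }
  detected <- profile$taxon_id[profile$rel_abundance > 0]
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  fn <- length(setdiff(truth, detected))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Aggregate a species-rank profile to genus rank
#'
#' Sums species read counts and abundances into their parent genera; total
#' abundance is conserved exactly.
#'
#' @param profile A species-rank `tax_profile`.
#' @param taxonomy Taxonomy tibble.
#' @return A genus-rank `tax_profile`.
#' @export
aggregate_to_genus <- function(profile, taxonomy) {
  if (profile_rank(profile) != "species") {
    stop("aggregate_to_genus needs a species-rank profile", call. = FALSE)
  }
  parent <- taxonomy$parent_id[match(profile$taxon_id, taxonomy$taxon_id)]
  prank <- taxonomy$rank[match(parent, taxonomy$taxon_id)]
  if (anyNA(parent) || any(prank != "genus")) {
    stop("species without a genus ancestor: ",
         paste(profile$taxon_id[is.na(parent) | prank != "genus"],
               collapse = ", "), call. = FALSE)
  }
  agg <- tibble(taxon_id = parent, read_count = profile$read_count) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(read_count = sum(.data$read_count), .groups = "drop")
  new_tax_profile(
    tibble(taxon_id = agg$taxon_id, rank = "genus",
           read_count = agg$read_count),
    "genus", unclassified_count(profile))
}

#' Spearman correlation matrix between taxonomic profiles
#'
#' Profiles are aligned on the union of taxa detected (abundance > 0) in at
#' least one profile; taxa absent from a profile enter as 0. Correlations
#' use average-rank tie handling; a pair involving a constant profile is
#' reported as `NA` (undefined), and the diagonal is 1.
#'
#' @param profiles Named list of `tax_profile`s (>= 2) at a common rank.
#' @return Symmetric matrix of Spearman correlations.
#' @export
profile_correlation <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  ranks <- unique(vapply(profiles, profile_rank, character(1)))
  if (length(ranks) != 1) stop("profiles must share a rank", call. = FALSE)
  taxa <- sort(unique(unlist(lapply(profiles, function(p) {
    p$taxon_id[p$rel_abundance > 0]
  }))))
  mat <- vapply(profiles, function(p) {
    v <- setNames(rep(0, length(taxa)), taxa)
    v[p$taxon_id[p$taxon_id %in% taxa]] <-
      p$rel_abundance[p$taxon_id %in% taxa]
    v
  }, numeric(length(taxa)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(taxa))
  out <- suppressWarnings(cor(mat, method = "spearman"))
  constant <- apply(mat, 2, function(x) length(unique(x)) == 1)
  out[constant, ] <- NA_real_
  out[, constant] <- NA_real_
  diag(out) <- 1
  dimnames(out) <- list(names(profiles), names(profiles))
  out
}

#' Trend of a metric against host fraction
#'
#' Spearman correlation of a per-sample metric (e.g. detected species
#' count) against the samples' host fractions, with a monotonicity verdict:
#' `"decreasing"` if the correlation is negative, `"increasing"` if
#' positive, `"flat"` if the metric is constant (correlation undefined).
#'
#' @param metric Numeric vector (one value per sample).
#' @param host_fraction Numeric vector of the samples' host fractions.
#' @return One-row tibble: `rho`, `verdict`, `n`.
#' @export
trend_vs_host_fraction <- function(metric, host_fraction) {
  if (length(metric) != length(host_fraction) || length(metric) < 4) {
    stop("need >= 4 paired samples", call. = FALSE)
  }
  if (length(unique(metric)) == 1) {
    return(tibble(rho = NA_real_, verdict = "flat", n = length(metric)))
  }
  rho <- suppressWarnings(cor(metric, host_fraction, method = "spearman"))
  tibble(rho = rho,
         verdict = if (is.na(rho)) "flat" else if (rho < 0) "decreasing"
                   else if (rho > 0) "increasing" else "flat",
         n = length(metric))
}

#' Per-sample evaluation report
#'
#' Scores a set of cleaned profiles against the ground-truth community and
#' stacks the metrics into the layout of a benchmarking figure: one row per
#' sample/method/setting.
#'
#' @param profiles Named list of `tax_profile`s; names are
#'   `"<sample>.<method>"` or arbitrary labels.
#' @param truth Character vector of expected taxa.
#' @param rank Evaluation rank.
#' @return Tibble with `label`, `n_detected`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluation_report <- function(profiles, truth, rank = "species") {
  purrr::imap_dfr(profiles, function(p, label) {
    dplyr::bind_cols(
      tibble(label = label, n_detected = sum(p$rel_abundance > 0)),
      score_profile(p, truth, rank))
  })
}

#' Plot an evaluation report
#'
#' @param report Output of [evaluation_report()].
#' @return A ggplot object (precision/recall/F1 bars per label).
#' @export
plot_metrics <- function(report) {
  df <- tidyr::pivot_longer(report, c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
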