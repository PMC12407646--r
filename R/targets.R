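# Filtering of multi-source miRNA-target interaction tables. The table
# schema and I/O live in R/io.R (read_interactions / write_interactions).

#' Keep the top-scoring predicted interactions of each source
#'
#' Predicted records survive iff their within-source score percentile is at
#' most `cutoff` (smaller percentile = better target site); validated
#' records are always kept. Raw scores of heterogeneous databases are not
#' comparable, which is why the table stores percentiles.
#'
#' @param table interaction tibble.
#' @param cutoff percentile cutoff in (0, 100].
#' @return filtered interaction tibble.
#' @export
filter_top_percentile <- function(table, cutoff = 10) {
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff <= 0 || cutoff > 100) {
    abort("cutoff must lie in (0, 100]")
  }
  table %>%
    filter(.data$evidence == "validated" | .data$score_percentile <= cutoff)
}

#' Pairs supported by validation or source agreement
#'
#' Retains a (miRNA, target) pair iff it carries at least one validated
#' record or predicted records from at least `min_predicted_sources`
#' distinct databases.
#'
#' @param table interaction tibble (filtered as desired).
#' @param min_predicted_sources distinct predicted-source floor.
#' @return tibble of retained pairs: columns mirna, target, n_sources,
#'   validated.
#' @export
support_filter <- function(table, min_predicted_sources = 2) {
  table %>%
    group_by(.data$mirna, .data$target) %>%
    summarise(
      n_sources = n_distinct(.data$source),
      validated = any(.data$evidence == "validated"),
      n_predicted_sources = n_distinct(.data$source[.data$evidence == "predicted"]),
      .groups = "drop"
    ) %>%
    filter(.data$validated |
             .data$n_predicted_sources >= min_predicted_sources) %>%
    select("mirna", "target", "n_sources", "validated") %>%
    arrange(.data$mirna, .data$target)
}

#' Aggregate an interaction table to one row per pair
#'
#' @param table interaction tibble.
#' @return tibble: mirna, target, n_sources (distinct), validated (any).
#' @export
aggregate_pairs <- function(table) {
  table %>%
    group_by(.data$mirna, .data$target) %>%
    summarise(
      n_sources = n_distinct(.data$source),
      validated = any(.data$evidence == "validated"),
      .groups = "drop"
    )
}
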