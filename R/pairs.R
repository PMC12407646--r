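#' Spearman rank correlation with midranks
#'
#' Pearson correlation of average-ranked values (midranks for ties). Returns
#' `NA` with a warning when either vector is constant, so callers can skip
#' the pair.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or NA for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Build the anti-correlated miRNA-mRNA pair table for one subtype
#'
#' Scores every (DE miRNA, DE mRNA) combination by the Spearman correlation
#' of their replicate-averaged temporal profiles and keeps pairs with
#' `rho < cutoff` (strict). Pairs present in the supplied interaction table
#' (after whatever filtering the caller applied) are flagged `annotated`
#' with their distinct source count and validation status; unannotated
#' anti-correlated pairs are retained but flagged, so both the
#' "negatively correlated" and the "annotated" network sizes are
#' reportable. miRNA ids are matched against the annotation
#' case-insensitively.
#'
#' @param mirna_profiles,mrna_profiles wide profile tibbles
#'   ([time_profiles()]) sharing the same ordered time points.
#' @param de_mirnas,de_mrnas DE feature ids (the pairing universe).
#' @param interactions interaction tibble used for annotation, or NULL.
#' @param cutoff Spearman threshold (strict; pairs kept iff rho < cutoff).
#' @param subtype subtype label stamped on the records.
#'
#' @return pair tibble: subtype, mirna, mrna, rho, n_timepoints, annotated,
#'   n_sources, validated, strong (FALSE; see [strong_pairs()]).
#' @export
build_pairs <- function(mirna_profiles, mrna_profiles, de_mirnas, de_mrnas,
                        interactions = NULL, cutoff = -0.5, subtype = NA_character_) {
  tp_a <- attr(mirna_profiles, "timepoints")
  tp_b <- attr(mrna_profiles, "timepoints")
  if (!identical(colnames(mirna_profiles), colnames(mrna_profiles)) ||
      (!is.null(tp_a) && !is.null(tp_b) && !identical(tp_a, tp_b))) {
    abort("miRNA and mRNA profiles must share the same ordered time points")
  }
  if (length(de_mirnas) == 0 || length(de_mrnas) == 0) {
    abort("DE feature sets must be non-empty")
  }
  ma <- profile_matrix(mirna_profiles)
  mb <- profile_matrix(mrna_profiles)
  de_mirnas <- intersect(de_mirnas, rownames(ma))
  de_mrnas <- intersect(de_mrnas, rownames(mb))
  a <- ma[de_mirnas, , drop = FALSE]
  b <- mb[de_mrnas, , drop = FALSE]
  n_tp <- ncol(a)

  rank_rows <- function(m) t(apply(m, 1, rank))
  ra <- rank_rows(a)
  rb <- rank_rows(b)
  ok_a <- apply(ra, 1, pop_sd) > 0
  ok_b <- apply(rb, 1, pop_sd) > 0
  if (any(!ok_a) || any(!ok_b)) {
    warn(paste0("skipping ", sum(!ok_a), " miRNA and ", sum(!ok_b),
                " mRNA constant profile(s)"))
  }
  rho <- suppressWarnings(cor(t(ra[ok_a, , drop = FALSE]),
                              t(rb[ok_b, , drop = FALSE])))

  hits <- which(rho < cutoff, arr.ind = TRUE)
  out <- tibble(
    subtype = subtype,
    mirna = rownames(rho)[hits[, 1]],
    mrna = colnames(rho)[hits[, 2]],
    rho = rho[hits],
    n_timepoints = n_tp
  )
  if (!is.null(interactions) && nrow(out) > 0) {
    ann <- aggregate_pairs(interactions) %>%
      mutate(mirna_key = canon_mirna(.data$mirna)) %>%
      select("mirna_key", mrna = "target", "n_sources", "validated")
    out <- out %>%
      mutate(mirna_key = canon_mirna(.data$mirna)) %>%
      left_join(ann, by = c("mirna_key", "mrna")) %>%
      mutate(
        annotated = !is.na(.data$n_sources),
        n_sources = ifelse(is.na(.data$n_sources), 0L, .data$n_sources),
        validated = ifelse(is.na(.data$validated), FALSE, .data$validated)
      ) %>%
      select(-"mirna_key")
  } else {
    out <- out %>%
      mutate(annotated = FALSE, n_sources = 0L, validated = FALSE)
  }
  out %>%
    mutate(strong = FALSE) %>%
    arrange(.data$mirna, .data$mrna)
}

#' Strongly anti-correlated annotated pairs
#'
#' @param pairs pair tibble from [build_pairs()].
#' @param cutoff strong-correlation threshold (strict; rho < cutoff).
#' @return subset with `annotated = TRUE` and `rho < cutoff`, `strong`
#'   flagged.
#' @export
strong_pairs <- function(pairs, cutoff = -0.7) {
  pairs %>%
    filter(.data$annotated, .data$rho < cutoff) %>%
    mutate(strong = TRUE)
}

#' Compare the annotated pair networks of two subtypes
#'
#' @param pairs_a,pairs_b pair tibbles of the two subtypes.
#' @return list with `shared_mirnas`, `a_only_mirnas`, `b_only_mirnas`
#'   (sorted character vectors) and `shared_pairs` (tibble mirna, mrna of
#'   pairs present in both).
#' @export
compare_subtypes <- function(pairs_a, pairs_b) {
  pa <- pairs_a %>% filter(.data$annotated)
  pb <- pairs_b %>% filter(.data$annotated)
  ma <- unique(pa$mirna)
  mb <- unique(pb$mirna)
  shared_pairs <- inner_join(
    pa %>% distinct(.data$mirna, .data$mrna),
    pb %>% distinct(.data$mirna, .data$mrna),
    by = c("mirna", "mrna")
  ) %>% arrange(.data$mirna, .data$mrna)
  list(
    shared_mirnas = sort(intersect(ma, mb)),
    a_only_mirnas = sort(setdiff(ma, mb)),
    b_only_mirnas = sort(setdiff(mb, ma)),
    shared_pairs = shared_pairs
  )
}

#' Rank hub miRNAs by both-subtype strong pairs
#'
#' For each miRNA, counts the (miRNA, mRNA) pairs that are strongly
#' anti-correlated and annotated in BOTH subtypes, ranks descending, and
#' breaks ties lexicographically by miRNA id.
#'
#' @param strong_a,strong_b strong-pair tibbles ([strong_pairs()]) of the
#'   two subtypes.
#' @return tibble: mirna, n_shared_strong_pairs, targets (list-column of
#'   shared target ids), ordered by rank.
#' @export
rank_hubs <- function(strong_a, strong_b) {
  shared <- inner_join(
    strong_a %>% distinct(.data$mirna, .data$mrna),
    strong_b %>% distinct(.data$mirna, .data$mrna),
    by = c("mirna", "mrna")
  )
  if (nrow(shared) == 0) {
    return(tibble(mirna = character(), n_shared_strong_pairs = integer(),
                  targets = list()))
  }
  shared %>%
    group_by(.data$mirna) %>%
    summarise(
      n_shared_strong_pairs = n(),
      targets = list(sort(.data$mrna)),
      .groups = "drop"
    ) %>%
    arrange(desc(.data$n_shared_strong_pairs), .data$mirna)
}
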