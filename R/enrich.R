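#' Hypergeometric upper-tail over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` marked items. The observed overlap `k` is
#' included in the tail (standard over-representation convention), so
#' `k = 0` gives p = 1. Vectorized over its arguments.
#'
#' @param k observed overlap.
#' @param K marked items in the universe (set size).
#' @param n drawn items (cluster / query size).
#' @param N universe size.
#' @return upper-tail p-value(s) in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) abort("K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n))) abort("k must lie in [0, min(K, n)]")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1
#' and mapped back to the input order.
#'
#' @param p_values raw p-values in [0, 1].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Target over-representation within temporal clusters
#'
#' One hypergeometric test per (DE miRNA, cluster): is the miRNA's annotated
#' target set over-represented among the cluster's genes, relative to the
#' universe of tested genes? Target sets are intersected with the universe;
#' miRNAs with no in-universe target are skipped with a warning. BH
#' adjustment runs jointly across all tests of the call.
#'
#' @param assignments cluster assignment tibble (feature, cluster), e.g.
#'   from [core_members()].
#' @param de_mirnas DE miRNA ids whose target sets are tested.
#' @param interactions interaction tibble supplying target sets (apply
#'   [filter_top_percentile()] / [support_filter()] upstream as desired).
#' @param universe background gene ids.
#' @param fdr_max significance threshold on the BH FDR (strict).
#' @return tibble: set_id, cluster_id, k, K, n, N, p_value, fdr,
#'   significant.
#' @export
target_enrichment <- function(assignments, de_mirnas, interactions, universe,
                              fdr_max = 0.05) {
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  targets_by_mirna <- interactions %>%
    mutate(mirna_key = canon_mirna(.data$mirna)) %>%
    filter(.data$mirna_key %in% canon_mirna(de_mirnas),
           .data$target %in% universe) %>%
    distinct(.data$mirna_key, .data$target)
  key_map <- setNames(de_mirnas, canon_mirna(de_mirnas))
  skipped <- setdiff(canon_mirna(de_mirnas), targets_by_mirna$mirna_key)
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " miRNA(s) with no target in the universe ",
                "were skipped"))
  }
  clusters <- assignments %>%
    filter(.data$feature %in% universe) %>%
    group_by(.data$cluster) %>%
    summarise(members = list(.data$feature), .groups = "drop")
  grid <- tidyr::expand_grid(
    mirna_key = unique(targets_by_mirna$mirna_key),
    cluster_id = clusters$cluster
  )
  if (nrow(grid) == 0) {
    return(tibble(set_id = character(), cluster_id = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric(),
                  significant = logical()))
  }
  tgt <- split(targets_by_mirna$target, targets_by_mirna$mirna_key)
  mem <- setNames(clusters$members, clusters$cluster)
  res <- grid %>%
    mutate(
      k = purrr::map2_int(.data$mirna_key, .data$cluster_id,
                          function(mk, cl) length(intersect(tgt[[mk]], mem[[cl]]))),
      K = lengths(tgt[.data$mirna_key]),
      n = lengths(mem[.data$cluster_id]),
      N = length(universe)
    ) %>%
    mutate(
      p_value = hypergeom_p(.data$k, .data$K, .data$n, .data$N),
      set_id = unname(key_map[.data$mirna_key])
    )
  res$fdr <- bh_adjust(res$p_value)
  res %>%
    mutate(significant = .data$fdr < fdr_max) %>%
    select("set_id", "cluster_id", "k", "K", "n", "N", "p_value", "fdr",
           "significant") %>%
    arrange(.data$fdr, .data$set_id, .data$cluster_id)
}

#' Fraction of each cluster targeted by DE miRNAs
#'
#' @param assignments cluster assignment tibble (feature, cluster).
#' @param targeted ids of genes targeted by at least one DE miRNA (the
#'   union of target sets).
#' @return tibble: cluster, n_features, n_targeted, fraction. Empty
#'   clusters cannot occur in assignment tables; an empty assignment table
#'   errors.
#' @export
fraction_targeted <- function(assignments, targeted) {
  if (nrow(assignments) == 0) {
    abort("empty cluster assignment: targeted fractions are undefined")
  }
  assignments %>%
    group_by(cluster = .data$cluster) %>%
    summarise(
      n_features = n(),
      n_targeted = sum(.data$feature %in% targeted),
      .groups = "drop"
    ) %>%
    mutate(fraction = .data$n_targeted / .data$n_features) %>%
    arrange(.data$cluster)
}

#' Gene-set over-representation from a GMT collection
#'
#' Hypergeometric upper-tail test of one query gene list against every set
#' of a collection, with BH adjustment across the collection. Sets with no
#' member in the universe are skipped.
#'
#' @param features query gene ids.
#' @param gene_sets collection tibble ([read_gmt()]): set_id, description,
#'   members.
#' @param universe background gene ids.
#' @param fdr_max significance threshold (strict).
#' @return tibble: set_id, cluster_id (NA), k, K, n, N, p_value, fdr,
#'   significant.
#' @export
ora_gene_sets <- function(features, gene_sets, universe, fdr_max = 0.05) {
  if (nrow(gene_sets) == 0) abort("empty gene-set collection")
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(features), universe)
  rows <- purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
    set <- intersect(gene_sets$members[[i]], universe)
    if (length(set) == 0) return(NULL)
    tibble(
      set_id = gene_sets$set_id[i],
      k = length(intersect(set, query)),
      K = length(set), n = length(query), N = length(universe)
    )
  })
  if (nrow(rows) == 0) abort("no gene set overlaps the universe")
  rows %>%
    mutate(
      cluster_id = NA_character_,
      p_value = hypergeom_p(.data$k, .data$K, .data$n, .data$N),
      fdr = bh_adjust(.data$p_value),
      significant = .data$fdr < fdr_max
    ) %>%
    select("set_id", "cluster_id", "k", "K", "n", "N", "p_value", "fdr",
           "significant") %>%
    arrange(.data$fdr, .data$set_id)
}
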