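# ggplot2 displays for the main result types.

#' Plot PCA sample coordinates
#'
#' @param object a `pca_profiles` object.
#' @param colour_by metadata column used for point colour (if present).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pca_profiles
#' @export
autoplot.pca_profiles <- function(object, colour_by = "day", ...) {
  sc <- object$scores
  ve <- object$var_explained
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (colour_by %in% names(sc)) {
    p <- ggplot2::ggplot(
      sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                       colour = factor(.data[[colour_by]]))
    ) + ggplot2::labs(colour = colour_by)
  }
  if ("subtype" %in% names(sc)) {
    p <- p + ggplot2::aes(shape = .data$subtype)
  }
  p + ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      title = "PCA of log10 normalized counts"
    ) +
    ggplot2::theme_minimal()
}

#' Plot soft-cluster temporal profiles
#'
#' Member profiles coloured by membership strength with the cluster
#' centroid overlaid, faceted by cluster.
#'
#' @param object fitted [fuzzy_cmeans()] model.
#' @param profiles the standardized profile tibble the model was fitted on.
#' @param min_membership show members at or above this membership.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fuzzy_cmeans
#' @export
autoplot.fuzzy_cmeans <- function(object, profiles, min_membership = 0.3, ...) {
  tp <- object$timepoints
  if (is.null(tp)) tp <- seq_len(ncol(object$centroids))
  members <- core_members(object, min_membership)
  long <- profiles %>%
    filter(.data$feature %in% members$feature) %>%
    tidyr::pivot_longer(-"feature", names_to = "time", values_to = "z") %>%
    left_join(members, by = "feature") %>%
    mutate(day = day_from_label(.data$time))
  cent <- matrix_to_tibble(object$centroids, id_col = "cluster") %>%
    tidyr::pivot_longer(-"cluster", names_to = "time", values_to = "z") %>%
    mutate(day = day_from_label(.data$time))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$z)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$feature,
                                    colour = .data$membership),
                       alpha = 0.5) +
    ggplot2::geom_line(data = cent, linewidth = 1.1, colour = "black") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "day", y = "standardized expression",
                  title = "Fuzzy c-means temporal clusters") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster targeted fractions
#'
#' @param fraction tibble from [fraction_targeted()] (optionally with a
#'   `subtype` column for faceting).
#' @return a ggplot.
#' @export
plot_targeted_fraction <- function(fraction) {
  p <- ggplot2::ggplot(
    fraction,
    ggplot2::aes(x = .data$cluster, y = .data$fraction)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_features), vjust = -0.3,
                       size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "cluster", y = "fraction targeted by DE miRNAs",
                  title = "mRNAs targeted by DE miRNAs per temporal cluster") +
    ggplot2::theme_minimal()
  if ("subtype" %in% names(fraction)) {
    p <- p + ggplot2::facet_wrap(~subtype)
  }
  p
}

#' Plot a pair-count summary for one or more subtypes
#'
#' Bars for negatively correlated, annotated, and strong pair counts.
#'
#' @param ... named pair tibbles from [build_pairs()], one per subtype.
#' @return a ggplot.
#' @export
plot_pair_summary <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(!nzchar(names(tabs)))) {
    abort("pass named pair tables, e.g. PMD = pairs_pmd")
  }
  dat <- purrr::imap_dfr(tabs, function(p, nm) {
    tibble(
      subtype = nm,
      class = c("negative", "annotated", "strong"),
      count = c(nrow(p), sum(p$annotated), sum(p$annotated & p$rho < -0.7))
    )
  }) %>%
    mutate(class = factor(.data$class,
                          levels = c("negative", "annotated", "strong")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$count,
                                    fill = .data$subtype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "pairs",
                  title = "miRNA-mRNA pair network sizes") +
    ggplot2::theme_minimal()
}
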