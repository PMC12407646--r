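#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the median-of-ratios
#' procedure: a pseudo-reference per feature is the geometric mean across
#' samples over features with nonzero counts in every sample; each sample's
#' factor is the median ratio of its counts to that reference. Factors are
#' rescaled to geometric mean 1 so normalized scales are comparable across
#' runs.
#'
#' @param counts counts tibble (first column `feature`).
#' @return tibble with columns `sample_id`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    abort(paste0(
      "no feature has nonzero counts in every sample; the median-of-ratios ",
      "reference cannot be computed (pseudo-reference fallback is disabled)"
    ))
  }
  lg <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- exp(apply(lg - loggeo, 2, median))
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Normalize counts by size factors
#'
#' Divides every sample column by its size factor.
#'
#' @param counts counts tibble.
#' @param size_factors tibble from [estimate_size_factors()].
#' @return tibble of the same shape with normalized (real-valued) counts.
#' @export
normalize_counts <- function(counts, size_factors) {
  m <- as_count_matrix(counts)
  idx <- match(colnames(m), size_factors$sample_id)
  if (anyNA(idx)) abort("size factors do not cover every sample")
  sf <- size_factors$size_factor[idx]
  if (any(sf <= 0)) abort("size factors must be positive")
  matrix_to_tibble(sweep(m, 2, sf, "/"))
}

#' Moderated negative-binomial Wald contrast
#'
#' Tests each feature for differential expression between one (subtype, day)
#' group and the control-day group of the same subtype. Group means are taken
#' on normalized counts; `log2fc = log2((mean_a + pc) / (mean_c + pc))` with
#' pseudocount `pc`. The NB dispersion is estimated per feature by the method
#' of moments from the pooled within-group variance and then floored at the
#' across-feature median dispersion (moderation: with few replicates the
#' per-feature variance is unstable, and below-median estimates are shrunk up
#' to the common value while above-median estimates are kept). The standard
#' error of the log2 fold change comes from the delta method on the NB
#' variance `mu + alpha * mu^2`, and `wald_p = 2 * (1 - Phi(|log2fc / se|))`.
#' Features with zero counts in both groups are flagged `all-zero` and not
#' tested. BH-adjusted p-values are reported alongside but DE calling uses
#' raw p-values (see [call_de()]).
#'
#' @param counts counts tibble.
#' @param metadata sample metadata tibble.
#' @param subtype,day the test group.
#' @param control_day day label of the control group (same subtype).
#' @param size_factors optional precomputed size factors; by default
#'   estimated on the full experiment.
#' @param pseudocount pseudocount on normalized group means.
#' @param dispersion_floor lower bound for the dispersion estimate.
#'
#' @return tibble with columns feature, base_mean, log2fc, se, wald_p, p_adj,
#'   status, subtype, day.
#' @export
nb_wald_contrast <- function(counts, metadata, subtype, day, control_day = -1,
                             size_factors = NULL, pseudocount = 0.5,
                             dispersion_floor = 1e-8) {
  m <- as_count_matrix(counts)
  check_metadata(metadata, colnames(m))
  sa <- metadata$sample_id[metadata$subtype == subtype & metadata$day == day]
  sc <- metadata$sample_id[metadata$subtype == subtype &
                             metadata$day == control_day]
  if (length(sa) == 0) abort(paste0("group (", subtype, ", day ", day,
                                    ") not found in metadata"))
  if (length(sc) == 0) abort(paste0("control group (", subtype, ", day ",
                                    control_day, ") not found in metadata"))
  if (length(sa) < 2 || length(sc) < 2) {
    abort("both groups need at least 2 samples")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- as_count_matrix(normalize_counts(counts, size_factors))

  a <- norm[, sa, drop = FALSE]
  c_ <- norm[, sc, drop = FALSE]
  na <- ncol(a); nc <- ncol(c_)
  ma <- rowMeans(a); mc <- rowMeans(c_)
  va <- apply(a, 1, var); vc <- apply(c_, 1, var)

  all_zero <- ma == 0 & mc == 0
  # method-of-moments dispersion from pooled within-group variance
  s2 <- ((na - 1) * va + (nc - 1) * vc) / (na + nc - 2)
  mg <- (ma + mc) / 2
  raw_alpha <- ifelse(mg > 0, (s2 - mg) / mg^2, NA_real_)
  raw_alpha <- pmax(dispersion_floor, raw_alpha)
  central <- median(raw_alpha[!all_zero & !is.na(raw_alpha)])
  if (!is.finite(central)) central <- dispersion_floor
  alpha <- pmax(raw_alpha, central)
  alpha[is.na(alpha)] <- central

  pc <- pseudocount
  lfc <- log2((ma + pc) / (mc + pc))
  var_ma <- (ma + alpha * ma^2) / na
  var_mc <- (mc + alpha * mc^2) / nc
  se <- sqrt(var_ma / ((ma + pc)^2 * log(2)^2) +
               var_mc / ((mc + pc)^2 * log(2)^2))
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  p[se == 0 & lfc == 0] <- 1

  out <- tibble(
    feature = rownames(norm),
    base_mean = unname(rowMeans(norm[, c(sa, sc), drop = FALSE])),
    log2fc = unname(lfc), se = unname(se), wald_p = unname(p),
    status = unname(ifelse(all_zero, "all-zero", "tested")),
    subtype = subtype, day = day
  )
  out$log2fc[all_zero] <- 0
  out$se[all_zero] <- NA_real_
  out$wald_p[all_zero] <- NA_real_
  out$p_adj <- NA_real_
  tested <- out$status == "tested"
  out$p_adj[tested] <- p.adjust(out$wald_p[tested], method = "BH")
  out %>% select("feature", "base_mean", "log2fc", "se", "wald_p", "p_adj",
                 "status", "subtype", "day")
}

#' Run every (subtype, day) vs control contrast
#'
#' @param counts,metadata as in [nb_wald_contrast()].
#' @param control_day control day label.
#' @param ... passed to [nb_wald_contrast()].
#' @return row-bound contrast tibble over all subtypes and non-control days.
#' @export
de_all_contrasts <- function(counts, metadata, control_day = -1, ...) {
  sf <- estimate_size_factors(counts)
  grid <- metadata %>%
    filter(.data$day != control_day) %>%
    distinct(.data$subtype, .data$day)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    nb_wald_contrast(counts, metadata, grid$subtype[i], grid$day[i],
                     control_day = control_day, size_factors = sf, ...)
  })
}

#' Call differentially expressed features
#'
#' Applies the calling rule: raw Wald p strictly below `p_max` and |log2FC|
#' strictly above `lfc_min`; boundary values are excluded.
#'
#' @param contrast contrast tibble from [nb_wald_contrast()] (may span
#'   several contrasts).
#' @param p_max p-value ceiling (strict).
#' @param lfc_min |log2FC| floor (strict).
#' @return tibble with columns subtype, day, direction ("up"/"down"),
#'   feature.
#' @export
call_de <- function(contrast, p_max = 0.05, lfc_min = 1.0) {
  contrast %>%
    filter(.data$status == "tested",
           .data$wald_p < p_max, abs(.data$log2fc) > lfc_min) %>%
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) %>%
    select("subtype", "day", "direction", "feature") %>%
    arrange(.data$subtype, .data$day, .data$direction, .data$feature)
}

#' Per-subtype union of DE features across days
#'
#' @param de_sets tibble from [call_de()].
#' @return tibble with columns subtype, feature (distinct).
#' @export
de_union <- function(de_sets) {
  de_sets %>% distinct(.data$subtype, .data$feature) %>%
    arrange(.data$subtype, .data$feature)
}

#' PCA of log10 normalized counts
#'
#' Samples are projected onto principal components of the
#' `log10(normalized + 1)` matrix with features centered; components come
#' from the singular value decomposition.
#'
#' @param normalized normalized counts tibble (first column `feature`).
#' @param metadata optional metadata joined onto the scores.
#' @param n_components number of components to report.
#' @return object of class `pca_profiles`: list with `scores` (tibble:
#'   sample_id, PC1, PC2, ..., plus metadata) and `var_explained` (fractions,
#'   non-increasing).
#' @export
pca_profiles <- function(normalized, metadata = NULL, n_components = 2) {
  m <- as_count_matrix(normalized)
  if (ncol(m) < 3) abort("PCA needs at least 3 samples")
  x <- t(log10(m + 1))                     # samples x features
  keep <- apply(x, 2, function(col) var(col) > 0)
  if (!any(keep)) abort("constant matrix: principal components are undefined")
  pr <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  scores <- as_tibble(pr$x[, seq_len(k), drop = FALSE]) %>%
    mutate(sample_id = rownames(x)) %>%
    select("sample_id", dplyr::everything())
  if (!is.null(metadata)) {
    scores <- left_join(scores, metadata, by = "sample_id")
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, var_explained = ve), class = "pca_profiles")
}

#' @export
print.pca_profiles <- function(x, ...) {
  cat("PCA of log10 normalized counts:", nrow(x$scores), "samples\n")
  cat("variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(head(x$var_explained, 4)),
                     100 * head(x$var_explained, 4)), collapse = ", "), "\n")
  invisible(x)
}
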