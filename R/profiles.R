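#' Replicate-averaged temporal expression profiles
#'
#' Averages normalized counts over replicates at each time point for one
#' subtype, yielding the feature-by-timepoint matrix that clustering and
#' correlation work on.
#'
#' @param normalized normalized counts tibble (first column `feature`).
#' @param metadata sample metadata.
#' @param subtype subtype to extract.
#' @param features optional feature subset (order preserved as given).
#' @param days optional day subset (defaults to all days of the subtype, in
#'   increasing order); lets the correlation window be restricted.
#'
#' @return wide tibble: `feature` plus one column per day label ("D-1",
#'   "D0", ...), with the ordered numeric days stored in the `timepoints`
#'   attribute.
#' @export
time_profiles <- function(normalized, metadata, subtype, features = NULL,
                          days = NULL) {
  m <- as_count_matrix(normalized)
  check_metadata(metadata, colnames(m))
  md <- metadata %>% filter(.data$subtype == !!subtype)
  if (nrow(md) == 0) abort(paste0("subtype not found: ", subtype))
  if (is.null(days)) days <- sort(unique(md$day))
  if (!all(days %in% md$day)) abort("requested days missing for this subtype")
  if (is.null(features)) features <- rownames(m)
  miss <- setdiff(features, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("unknown feature(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  prof <- vapply(days, function(d) {
    s <- md$sample_id[md$day == d]
    rowMeans(m[features, s, drop = FALSE])
  }, numeric(length(features)))
  prof <- matrix(prof, nrow = length(features),
                 dimnames = list(features, day_label(days)))
  out <- matrix_to_tibble(prof)
  attr(out, "timepoints") <- days
  out
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, -1, drop = FALSE])
  rownames(m) <- profiles$feature
  m
}

#' Z-standardize temporal profiles
#'
#' Scales every feature row to mean 0 and population standard deviation 1
#' across time points. Rows with zero variance carry no temporal shape and
#' are dropped with a message.
#'
#' @param profiles wide profile tibble from [time_profiles()].
#' @return standardized profile tibble (possibly fewer rows); dropped
#'   features are recorded in the `dropped` attribute.
#' @export
standardize_profiles <- function(profiles) {
  m <- profile_matrix(profiles)
  if (ncol(m) < 2) abort("standardization needs at least two time points")
  z <- zscale_rows(m)
  flat <- !is.finite(rowSums(z))
  if (all(flat)) abort("all profiles are constant; nothing to standardize")
  if (any(flat)) {
    rlang::inform(paste0("dropping ", sum(flat), " constant profile(s)"))
  }
  out <- matrix_to_tibble(z[!flat, , drop = FALSE])
  attr(out, "timepoints") <- attr(profiles, "timepoints")
  attr(out, "dropped") <- rownames(m)[flat]
  out
}

#' Fuzzifier heuristic for fuzzy c-means
#'
#' Data-driven choice of the fuzzifier `m` from the number of features `N`
#' and time points `D`:
#' `m = 1 + (1418/N + 22.05) * D^-2 +
#'      (12.33/N + 0.243) * D^(-0.0406 * ln N - 0.1134)`.
#' Always exceeds 1; decreases toward its D-only terms as N grows.
#'
#' @param profiles standardized profile tibble (>= 3 features).
#' @return the fuzzifier `m` (> 1).
#' @export
estimate_fuzzifier <- function(profiles) {
  n_feat <- nrow(profiles)
  n_dim <- ncol(profiles) - 1
  if (n_dim < 2) abort("fuzzifier heuristic needs at least 2 time points")
  if (n_feat < 3) abort("fuzzifier heuristic needs at least 3 features")
  1 + (1418 / n_feat + 22.05) * n_dim^(-2) +
    (12.33 / n_feat + 0.243) *
      n_dim^(-0.0406 * log(n_feat) - 0.1134)
}
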