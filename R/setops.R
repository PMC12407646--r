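#' Exclusive intersections of a set family
#'
#' Computes UpSet-style exclusive intersections: every element of the union
#' contributes to exactly one signature — the exact subset of family members
#' containing it — and signatures are counted. Empty signatures are
#' omitted. Output is sorted by count (descending), then by signature.
#'
#' @param family named list of vectors (e.g. DE sets keyed by
#'   "subtype_day_direction").
#' @return tibble: signature (keys joined by "&", keys sorted), degree
#'   (number of keys), count, members (list-column).
#' @export
exclusive_intersections <- function(family) {
  if (length(family) == 0) abort("family must contain at least one set")
  if (is.null(names(family)) || any(!nzchar(names(family)))) {
    abort("family sets must be named")
  }
  if (anyDuplicated(names(family))) abort("family keys must be unique")
  keys <- names(family)
  universe <- unique(unlist(family, use.names = FALSE))
  if (length(universe) == 0) {
    return(tibble(signature = character(), degree = integer(),
                  count = integer(), members = list()))
  }
  inc <- vapply(family, function(s) universe %in% s, logical(length(universe)))
  inc <- matrix(inc, nrow = length(universe), dimnames = list(universe, keys))
  sig <- apply(inc, 1, function(r) paste(sort(keys[r]), collapse = "&"))
  split_members <- split(universe, sig)
  tibble(
    signature = names(split_members),
    degree = unname(lengths(strsplit(names(split_members), "&", fixed = TRUE))),
    count = unname(lengths(split_members)),
    members = unname(lapply(split_members, sort))
  ) %>%
    arrange(desc(.data$count), .data$signature)
}

#' Elements unique to one set of a family
#'
#' @param family named list of vectors.
#' @param key the set of interest.
#' @return sorted vector of elements in `family[[key]]` and in no other set.
#' @export
unique_signature <- function(family, key) {
  if (!key %in% names(family)) abort(paste0("unknown key: ", key))
  others <- unique(unlist(family[setdiff(names(family), key)],
                          use.names = FALSE))
  sort(setdiff(unique(family[[key]]), others))
}
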