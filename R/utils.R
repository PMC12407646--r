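# Internal helpers shared across modules.

# Convert a counts tibble (first column = feature id, remaining columns =
# samples) to an integer matrix with feature rownames.
as_count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1]])
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

matrix_to_tibble <- function(m, id_col = "feature") {
  out <- as_tibble(m, rownames = id_col)
  out
}

# "D-1", "D0", ..., "D16"
day_label <- function(day) paste0("D", day)

# Parse "D-1" -> -1L
day_from_label <- function(lab) as.integer(sub("^D", "", lab))

check_metadata <- function(metadata, samples = NULL) {
  req <- c("sample_id", "subtype", "day", "replicate")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0) {
    abort(paste0("metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) abort("duplicate sample_id in metadata")
  if (!is.null(samples)) {
    if (!setequal(samples, metadata$sample_id)) {
      abort("metadata does not cover the count matrix samples exactly once")
    }
  }
  invisible(metadata)
}

# miRNA ids are matched case-insensitively after trimming.
canon_mirna <- function(x) stringr::str_to_lower(stringr::str_trim(x))

# Population (divide-by-n) standard deviation used for profile z-scaling.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Row-wise z-scale with population sd; rows with sd 0 get NA.
zscale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  sweep(sweep(m, 1, mu, "-"), 1, s, "/")
}
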