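# Plain-text I/O for every table the pipeline consumes or writes.
# Counts: TSV, first column `feature`, remaining columns sample ids.
# Metadata: TSV with sample_id, subtype, day, replicate.
# Interactions: TSV with mirna, target, source, evidence, score_percentile.
# Gene sets: standard GMT. Ground truth / reports: JSON.

#' Read / write a counts table
#'
#' @param path file path.
#' @return [read_counts()] returns a tibble whose first column is `feature`.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "feature"
  out
}

#' @rdname read_counts
#' @param counts counts tibble (first column feature ids).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' @param path file path.
#' @return tibble with columns sample_id, subtype, day, replicate.
#' @export
read_sample_metadata <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", subtype = "c",
                           day = "d", replicate = "i"
                         ))
  check_metadata(out)
  out
}

#' @rdname read_sample_metadata
#' @param metadata metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  check_metadata(metadata)
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' Read a multi-source miRNA-target interaction table
#'
#' Validates the schema (`mirna`, `target`, `source`, `evidence`,
#' `score_percentile`), rejects unknown evidence values and out-of-range
#' percentiles with the offending line numbers, trims and lower-cases miRNA
#' ids for matching, and collapses duplicate (mirna, target, source) triples
#' keeping the best (smallest) percentile.
#'
#' @param path TSV file path.
#' @return interaction tibble.
#' @export
read_interactions <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           mirna = "c", target = "c", source = "c",
                           evidence = "c", score_percentile = "d"
                         ))
  req <- c("mirna", "target", "source", "evidence", "score_percentile")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    abort(paste0("interaction table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  validate_interactions(raw)
}

#' Validate and canonicalize an in-memory interaction table
#'
#' @param table interaction tibble.
#' @return canonicalized interaction tibble.
#' @export
validate_interactions <- function(table) {
  bad_ev <- which(!table$evidence %in% c("validated", "predicted"))
  if (length(bad_ev) > 0) {
    abort(paste0("unknown evidence value(s) at row(s): ",
                 paste(head(bad_ev, 5), collapse = ", ")))
  }
  pred <- table$evidence == "predicted"
  bad_sc <- which(pred & (is.na(table$score_percentile) |
                            table$score_percentile <= 0 |
                            table$score_percentile > 100))
  if (length(bad_sc) > 0) {
    abort(paste0("predicted records need a score percentile in (0, 100]; ",
                 "bad row(s): ", paste(head(bad_sc, 5), collapse = ", ")))
  }
  bad_id <- which(is.na(table$mirna) | is.na(table$target) | is.na(table$source))
  if (length(bad_id) > 0) {
    abort(paste0("malformed row(s) with missing ids: ",
                 paste(head(bad_id, 5), collapse = ", ")))
  }
  table %>%
    mutate(
      mirna = stringr::str_to_lower(stringr::str_trim(.data$mirna)),
      target = stringr::str_trim(.data$target)
    ) %>%
    arrange(.data$mirna, .data$target, .data$source, .data$score_percentile) %>%
    distinct(.data$mirna, .data$target, .data$source, .keep_all = TRUE)
}

#' @rdname read_interactions
#' @param table interaction tibble.
#' @export
write_interactions <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line holds a set name, a description, and tab-separated member
#' ids.
#'
#' @param path GMT file path.
#' @return tibble with columns `set_id`, `description`, `members`
#'   (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line(s) with fewer than 3 fields: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  tibble(
    set_id = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, `[`, character(1), 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param gene_sets tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$set_id[i], gene_sets$description[i],
            gene_sets$members[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth `ground_truth` object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      regulator_ids = truth$regulator_ids,
      true_pairs = truth$true_pairs,
      prototype_assignment = truth$prototype_assignment,
      de_features = truth$de_features,
      hub_regulator = truth$hub_regulator
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    regulator_ids = x$regulator_ids,
    true_pairs = as_tibble(x$true_pairs),
    prototype_assignment = as_tibble(x$prototype_assignment),
    de_features = as_tibble(x$de_features),
    hub_regulator = x$hub_regulator
  ), class = "ground_truth")
}
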