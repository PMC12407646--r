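#' Pipeline configuration
#'
#' One declarative object holding every threshold of the integration
#' pipeline with its conventional default: per-time-point DE calling at raw
#' p < 0.05 and |log2FC| > 1, pairing at Spearman rho < -0.5, strong pairs
#' at rho < -0.7, annotation restricted to the top 10% predicted target
#' sites per source, optional support filtering at >= 2 distinct predicted
#' sources (or validation), BH FDR < 0.05 for enrichment, 8 temporal
#' clusters with argmax assignment at membership >= 0.5.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; all stage seeds derive from it.
#' @param sim [sim_config()] for the synthetic inputs (its seed is
#'   overridden by `seed`), or NULL when counts/annotation paths are given.
#' @param counts_mirna,counts_mrna,metadata_path,interactions_path optional
#'   paths to externally produced inputs (all four required together).
#' @param gene_sets_path optional GMT collection for pathway ORA.
#' @param p_max,lfc_min DE calling thresholds (strict inequalities).
#' @param rho_cutoff,strong_cutoff pairing thresholds (strict).
#' @param top_percent per-source predicted-score percentile cutoff.
#' @param min_sources distinct predicted sources for the refined support
#'   filter.
#' @param apply_support_filter use the support filter for the main network
#'   (default keeps it as the refinement stage only).
#' @param fdr_max enrichment significance threshold.
#' @param n_clusters fuzzy c-means cluster count per subtype.
#' @param min_membership core-member assignment threshold.
#' @param control_day control day label.
#' @param correlation_days optional day subset for the correlation window
#'   (default: all days).
#'
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("tempomir_run_"), seed = 1,
                            sim = sim_config(),
                            counts_mirna = NULL, counts_mrna = NULL,
                            metadata_path = NULL, interactions_path = NULL,
                            gene_sets_path = NULL,
                            p_max = 0.05, lfc_min = 1.0,
                            rho_cutoff = -0.5, strong_cutoff = -0.7,
                            top_percent = 10, min_sources = 2,
                            apply_support_filter = FALSE,
                            fdr_max = 0.05, n_clusters = 8,
                            min_membership = 0.5, control_day = -1,
                            correlation_days = NULL) {
  stopifnot(p_max > 0, p_max <= 1, lfc_min >= 0,
            rho_cutoff >= -1.5, strong_cutoff >= -1.5,
            top_percent > 0, top_percent <= 100,
            fdr_max > 0, fdr_max <= 1, n_clusters >= 1,
            min_membership >= 0, min_membership <= 1)
  ext <- list(counts_mirna, counts_mrna, metadata_path, interactions_path)
  if (any(!vapply(ext, is.null, logical(1))) &&
      any(vapply(ext, is.null, logical(1)))) {
    abort("external inputs require all of counts_mirna, counts_mrna, metadata_path, interactions_path")
  }
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim,
    counts_mirna = counts_mirna, counts_mrna = counts_mrna,
    metadata_path = metadata_path, interactions_path = interactions_path,
    gene_sets_path = gene_sets_path,
    p_max = p_max, lfc_min = lfc_min, rho_cutoff = rho_cutoff,
    strong_cutoff = strong_cutoff, top_percent = top_percent,
    min_sources = min_sources, apply_support_filter = apply_support_filter,
    fdr_max = fdr_max, n_clusters = n_clusters,
    min_membership = min_membership, control_day = control_day,
    correlation_days = correlation_days
  ), class = "pipeline_config")
}

#' Run the full integration pipeline
#'
#' Executes every stage end-to-end — simulate (or load) the two count
#' layers, normalize, per-time-point DE in both layers, soft-cluster the DE
#' mRNA profiles per subtype, filter the annotation table, build the
#' anti-correlated pair network, compute target enrichment within clusters
#' and per-cluster targeted fractions, UpSet-style DE miRNA intersections,
#' cross-subtype comparison and hub ranking — writing each stage's table
#' under `out_dir` with stable names and returning a machine-readable run
#' report whose counts are audited against the written tables. Reruns with
#' the same configuration reproduce identical outputs (the report isolates
#' volatile state in its single `timestamp` field).
#'
#' @param config a [pipeline_config()].
#' @return the run report (list of class `run_report`), invisibly also
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$counts_mirna)) {
    mirna_counts <- read_counts(cfg$counts_mirna)
    mrna_counts <- read_counts(cfg$counts_mrna)
    metadata <- read_sample_metadata(cfg$metadata_path)
    interactions <- read_interactions(cfg$interactions_path)
  } else {
    sim <- simulate_experiment(cfg$sim)
    mirna_counts <- sim$mirna_counts
    mrna_counts <- sim$mrna_counts
    metadata <- sim$metadata
    truth <- sim$truth
    interactions <- simulate_annotation(truth, cfg$sim)
    write_counts(mirna_counts, out("mirna_counts.tsv"))
    write_counts(mrna_counts, out("mrna_counts.tsv"))
    write_sample_metadata(metadata, out("metadata.tsv"))
    write_interactions(interactions, out("interactions.tsv"))
    write_ground_truth(truth, out("ground_truth.json"))
  }
  subtypes <- sort(unique(metadata$subtype))

  # ---- normalization ------------------------------------------------------
  sf_mirna <- estimate_size_factors(mirna_counts)
  sf_mrna <- estimate_size_factors(mrna_counts)
  norm_mirna <- normalize_counts(mirna_counts, sf_mirna)
  norm_mrna <- normalize_counts(mrna_counts, sf_mrna)
  readr::write_tsv(sf_mirna, out("size_factors_mirna.tsv"))
  readr::write_tsv(sf_mrna, out("size_factors_mrna.tsv"))

  # ---- differential expression -------------------------------------------
  ct_mirna <- de_all_contrasts(mirna_counts, metadata,
                               control_day = cfg$control_day)
  ct_mrna <- de_all_contrasts(mrna_counts, metadata,
                              control_day = cfg$control_day)
  de_mirna <- call_de(ct_mirna, cfg$p_max, cfg$lfc_min)
  de_mrna <- call_de(ct_mrna, cfg$p_max, cfg$lfc_min)
  readr::write_tsv(ct_mirna, out("contrasts_mirna.tsv"))
  readr::write_tsv(ct_mrna, out("contrasts_mrna.tsv"))
  readr::write_tsv(de_mirna, out("de_sets_mirna.tsv"))
  readr::write_tsv(de_mrna, out("de_sets_mrna.tsv"))
  union_mirna <- de_union(de_mirna)
  union_mrna <- de_union(de_mrna)

  # ---- annotation filtering ----------------------------------------------
  interactions_top <- filter_top_percentile(interactions, cfg$top_percent)
  network_annotation <- if (cfg$apply_support_filter) {
    supported <- support_filter(interactions_top, cfg$min_sources)
    interactions_top %>%
      semi_join(supported, by = c("mirna", "target"))
  } else {
    interactions_top
  }
  refined_pairs <- support_filter(interactions_top, cfg$min_sources)
  readr::write_tsv(refined_pairs, out("supported_pairs.tsv"))

  # ---- per-subtype clustering, pairing, enrichment ------------------------
  per_subtype <- list()
  for (st in subtypes) {
    de_mi <- union_mirna$feature[union_mirna$subtype == st]
    de_mr <- union_mrna$feature[union_mrna$subtype == st]
    if (length(de_mi) == 0 || length(de_mr) == 0) {
      per_subtype[[st]] <- list(empty = TRUE, de_mirnas = de_mi,
                                de_mrnas = de_mr)
      next
    }
    prof_mr_all <- time_profiles(norm_mrna, metadata, st, features = de_mr)
    prof_z <- standardize_profiles(prof_mr_all)
    fit <- fuzzy_cmeans(prof_z, c = min(cfg$n_clusters, nrow(prof_z)),
                        seed = cfg$seed + 10L)
    members <- core_members(fit, cfg$min_membership)
    readr::write_tsv(tidy(fit), out(paste0("membership_", st, ".tsv")))
    readr::write_tsv(matrix_to_tibble(fit$centroids, id_col = "cluster"),
                     out(paste0("centroids_", st, ".tsv")))
    readr::write_tsv(members, out(paste0("cluster_assignment_", st, ".tsv")))

    corr_days <- cfg$correlation_days
    prof_mi <- time_profiles(norm_mirna, metadata, st, features = de_mi,
                             days = corr_days)
    prof_mr <- time_profiles(norm_mrna, metadata, st, features = de_mr,
                             days = corr_days)
    pairs <- build_pairs(prof_mi, prof_mr, de_mi, de_mr,
                         interactions = network_annotation,
                         cutoff = cfg$rho_cutoff, subtype = st)
    strong <- strong_pairs(pairs, cfg$strong_cutoff)
    readr::write_tsv(pairs, out(paste0("pairs_", st, ".tsv")))
    readr::write_tsv(strong, out(paste0("strong_pairs_", st, ".tsv")))

    universe <- ct_mrna %>%
      filter(.data$subtype == st, .data$status == "tested") %>%
      distinct(.data$feature) %>% pull("feature")
    enr <- target_enrichment(members, de_mi, network_annotation, universe,
                             cfg$fdr_max)
    targeted <- network_annotation %>%
      filter(canon_mirna(.data$mirna) %in% canon_mirna(de_mi)) %>%
      pull("target") %>% unique()
    frac <- fraction_targeted(members, targeted)
    readr::write_tsv(enr, out(paste0("target_enrichment_", st, ".tsv")))
    readr::write_tsv(frac, out(paste0("fraction_targeted_", st, ".tsv")))

    ora <- NULL
    if (!is.null(cfg$gene_sets_path)) {
      gs <- read_gmt(cfg$gene_sets_path)
      ora <- ora_gene_sets(de_mr, gs, universe, cfg$fdr_max)
      readr::write_tsv(ora, out(paste0("ora_gene_sets_", st, ".tsv")))
    }

    per_subtype[[st]] <- list(
      empty = FALSE, de_mirnas = de_mi, de_mrnas = de_mr, fit = fit,
      members = members, pairs = pairs, strong = strong, enrichment = enr,
      fraction = frac, ora = ora
    )
  }

  # ---- set intersections over DE miRNA sets -------------------------------
  fam <- de_mirna %>%
    mutate(key = paste(.data$subtype, day_label(.data$day), .data$direction,
                       sep = "_"))
  family <- split(fam$feature, fam$key)
  upset <- if (length(family) > 0) exclusive_intersections(family) else NULL
  if (!is.null(upset)) {
    readr::write_tsv(upset %>% select(-"members"), out("upset_signatures.tsv"))
  }

  # ---- cross-subtype comparison and hubs ----------------------------------
  comparison <- NULL
  hubs <- NULL
  if (length(subtypes) >= 2) {
    a <- per_subtype[[subtypes[1]]]
    b <- per_subtype[[subtypes[2]]]
    if (!a$empty && !b$empty) {
      comparison <- compare_subtypes(a$pairs, b$pairs)
      hubs <- rank_hubs(a$strong, b$strong)
      jsonlite::write_json(
        list(
          subtype_a = subtypes[1], subtype_b = subtypes[2],
          n_shared_mirnas = length(comparison$shared_mirnas),
          n_a_only_mirnas = length(comparison$a_only_mirnas),
          n_b_only_mirnas = length(comparison$b_only_mirnas),
          n_shared_pairs = nrow(comparison$shared_pairs),
          shared_mirnas = comparison$shared_mirnas
        ),
        out("subtype_comparison.json"), auto_unbox = TRUE, pretty = TRUE
      )
      readr::write_tsv(
        hubs %>% mutate(targets = purrr::map_chr(.data$targets, paste,
                                                 collapse = ";")),
        out("hub_ranking.tsv")
      )
    }
  }

  # ---- report -------------------------------------------------------------
  report <- structure(list(
    package = "tempomir",
    version = as.character(utils::packageVersion("tempomir")),
    seed = cfg$seed,
    thresholds = cfg[c("p_max", "lfc_min", "rho_cutoff", "strong_cutoff",
                       "top_percent", "min_sources", "fdr_max",
                       "n_clusters", "min_membership")],
    subtypes = as.list(setNames(lapply(subtypes, function(st) {
      s <- per_subtype[[st]]
      de_by_day <- de_mirna %>% filter(.data$subtype == st) %>%
        count(.data$day) %>% (function(d) setNames(as.list(d$n), day_label(d$day)))
      list(
        n_de_mirnas = length(s$de_mirnas),
        n_de_mrnas = length(s$de_mrnas),
        de_mirnas_by_day = de_by_day,
        n_negative_pairs = if (s$empty) 0L else nrow(s$pairs),
        n_annotated_pairs = if (s$empty) 0L else sum(s$pairs$annotated),
        n_strong_pairs = if (s$empty) 0L else nrow(s$strong),
        n_pair_mirnas = if (s$empty) 0L else
          dplyr::n_distinct(s$pairs$mirna[s$pairs$annotated]),
        n_clusters = if (s$empty) 0L else s$fit$c,
        cluster_sizes = if (s$empty) list() else
          as.list(table(s$members$cluster)),
        targeted_fraction_range = if (s$empty) NULL else
          range(s$fraction$fraction)
      )
    }), subtypes)),
    shared = if (is.null(comparison)) NULL else list(
      n_shared_mirnas = length(comparison$shared_mirnas),
      n_shared_pairs = nrow(comparison$shared_pairs),
      hub_mirna = if (nrow(hubs) > 0) hubs$mirna[1] else NA_character_,
      hub_n_shared_strong_pairs = if (nrow(hubs) > 0)
        hubs$n_shared_strong_pairs[1] else 0L
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")

  audit_report(report, cfg$out_dir)
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Count-consistency audit: the report's headline counts must match the
# written stage tables. Aborts on any mismatch.
audit_report <- function(report, out_dir) {
  for (st in names(report$subtypes)) {
    s <- report$subtypes[[st]]
    pairs_path <- file.path(out_dir, paste0("pairs_", st, ".tsv"))
    if (file.exists(pairs_path)) {
      pairs <- readr::read_tsv(pairs_path, show_col_types = FALSE,
                               progress = FALSE)
      if (nrow(pairs) != s$n_negative_pairs ||
          sum(as.logical(pairs$annotated)) != s$n_annotated_pairs) {
        abort(paste0("audit failure: pair counts disagree for ", st))
      }
    }
    de_path <- file.path(out_dir, "de_sets_mirna.tsv")
    if (file.exists(de_path)) {
      de <- readr::read_tsv(de_path, show_col_types = FALSE, progress = FALSE)
      n_de <- dplyr::n_distinct(de$feature[de$subtype == st])
      if (n_de != s$n_de_mirnas) {
        abort(paste0("audit failure: DE miRNA count disagrees for ", st))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tempomir run (seed", x$seed, ")\n")
  for (st in names(x$subtypes)) {
    s <- x$subtypes[[st]]
    cat(sprintf(
      "  %s: %d DE miRNAs, %d DE mRNAs, %d negative pairs (%d annotated, %d strong)\n",
      st, s$n_de_mirnas, s$n_de_mrnas, s$n_negative_pairs,
      s$n_annotated_pairs, s$n_strong_pairs))
  }
  if (!is.null(x$shared)) {
    cat(sprintf("  shared: %d miRNAs, %d pairs; hub %s (%d shared strong pairs)\n",
                x$shared$n_shared_mirnas, x$shared$n_shared_pairs,
                x$shared$hub_mirna, x$shared$hub_n_shared_strong_pairs))
  }
  invisible(x)
}
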