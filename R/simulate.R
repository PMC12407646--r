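#' Simulation configuration for a two-subtype senescence time course
#'
#' Bundles every knob of the synthetic-data generator: the size of the miRNA
#' and mRNA layers, the planted repressor structure, the time grid, replicate
#' and subtype layout, negative-binomial noise, and the annotation-table
#' composition. Defaults emulate a design with duplicate samples at nine time
#' points (a proliferating control at day -1 plus days 0-16 after senescence
#' induction) in two subtypes, with 20 planted repressor miRNAs.
#'
#' @param n_mirna,n_mrna number of miRNA / mRNA features.
#' @param n_regulators number of planted repressor miRNAs (`<= n_mirna`).
#' @param targets_per_regulator planted targets per regulator.
#' @param hub_bonus_targets extra targets granted to the first regulator so a
#'   single ground-truth hub is identifiable; set to 0 for a fully symmetric
#'   design.
#' @param timepoints strictly increasing day labels; the first entry is the
#'   proliferating control day.
#' @param n_replicates replicates per (subtype, day); at least 2.
#' @param subtypes condition labels (two by default).
#' @param n_prototypes number of planted temporal prototype shapes.
#' @param baseline_mean expected count of an average feature at the control day.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`).
#' @param effect_log2fc planted log2 fold-change amplitude multiplying the
#'   prototype z-shape.
#' @param decoy_fraction fraction of annotation records that are decoys
#'   (pairs not in the ground truth).
#' @param n_sources number of synthetic annotation databases.
#' @param frac_multi_source fraction of true pairs predicted by >= 2 distinct
#'   sources.
#' @param frac_validated fraction of true pairs carrying a validated record.
#' @param true_max_percentile upper bound of the score percentile assigned to
#'   predicted records of true pairs (genuine targets rank near the top of
#'   each database).
#' @param baseline_sdlog log-normal sd of per-feature baseline means.
#' @param seed integer seed; identical configurations reproduce identical
#'   outputs bit for bit.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirna = 100, n_mrna = 2000,
                       n_regulators = 20, targets_per_regulator = 30,
                       hub_bonus_targets = 10,
                       timepoints = c(-1, 0, 1, 2, 3, 4, 6, 8, 16),
                       n_replicates = 2, subtypes = c("PMD", "DDR"),
                       n_prototypes = 8, baseline_mean = 200,
                       dispersion = 0.1, effect_log2fc = 2,
                       decoy_fraction = 0.3, n_sources = 14,
                       frac_multi_source = 0.8, frac_validated = 0.3,
                       true_max_percentile = 10, baseline_sdlog = 0.6,
                       seed = 1) {
  cfg <- list(
    n_mirna = n_mirna, n_mrna = n_mrna, n_regulators = n_regulators,
    targets_per_regulator = targets_per_regulator,
    hub_bonus_targets = hub_bonus_targets,
    timepoints = timepoints, n_replicates = n_replicates,
    subtypes = subtypes, n_prototypes = n_prototypes,
    baseline_mean = baseline_mean, dispersion = dispersion,
    effect_log2fc = effect_log2fc, decoy_fraction = decoy_fraction,
    n_sources = n_sources, frac_multi_source = frac_multi_source,
    frac_validated = frac_validated,
    true_max_percentile = true_max_percentile,
    baseline_sdlog = baseline_sdlog, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_regulators > cfg$n_mirna) {
    abort("n_regulators must not exceed n_mirna")
  }
  n_targets <- cfg$n_regulators * cfg$targets_per_regulator + cfg$hub_bonus_targets
  if (n_targets > cfg$n_mrna) {
    abort("planted targets exceed n_mrna")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  if (cfg$n_replicates < 2) abort("n_replicates must be at least 2")
  if (is.unsorted(cfg$timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1) {
    abort("decoy_fraction must lie in [0, 1)")
  }
  invisible(cfg)
}

# Deterministic archetype shapes over T ordered time points: four base
# motifs (monotone trend, early / mid / late transient peaking at fixed grid
# positions) and their negations. The early peak culminates at the first
# post-control day (index 2 when a control day leads the grid). Base motifs
# are mutually |cor| <= 0.7, so the signed pairwise ceiling holds for all 8.
prototype_archetypes <- function(n_time) {
  i <- seq_len(n_time)
  u <- seq(0, 1, length.out = n_time)
  g <- function(i0, w) exp(-((i - i0) / w)^2)
  # small monotone tilts keep the transient shapes' values strictly distinct
  # (no tied planted means) while staying inside the correlation ceiling
  early <- g(min(2, n_time), 0.9) + 0.12 * u
  mid <- g((n_time + 1) / 2, 1.2) + 0.18 * u
  late <- g(n_time - 1, 0.9) - 0.12 * u
  list(
    monotone_up   = u,
    monotone_down = -u,
    early_peak    = early,
    early_trough  = -early,
    mid_peak      = mid,
    mid_trough    = -mid,
    late_peak     = late,
    late_trough   = -late
  )
}

#' Generate planted temporal prototype shapes
#'
#' Produces `n_prototypes` z-scaled temporal shapes (rows: mean 0, population
#' sd 1) over the given time grid. The first shapes are fixed archetypes
#' (monotone up, monotone down, early peak at the first post-control day,
#' early trough, ...); any further shapes are smoothed random walks accepted
#' only when their Pearson correlation with every already-accepted shape is
#' at most `max_cor`.
#'
#' @param n_prototypes number of shapes (>= 1).
#' @param timepoints ordered day labels (numeric).
#' @param seed integer seed.
#' @param max_cor pairwise Pearson correlation ceiling between shapes.
#' @param max_attempts resampling budget per random shape.
#'
#' @return A numeric matrix `n_prototypes x length(timepoints)` with
#'   rownames `P1..Pk` and colnames `D-1, D0, ...`.
#' @export
make_prototypes <- function(n_prototypes, timepoints = c(-1, 0, 1, 2, 3, 4, 6, 8, 16),
                            seed = 1, max_cor = 0.7, max_attempts = 500) {
  if (n_prototypes < 1) abort("n_prototypes must be >= 1")
  n_time <- length(timepoints)
  if (n_time < 2) abort("need at least two time points")
  arch <- prototype_archetypes(n_time)
  base <- do.call(rbind, arch[seq_len(min(n_prototypes, length(arch)))])
  base <- zscale_rows(base)
  rows <- lapply(seq_len(nrow(base)), function(i) base[i, ])
  # correlations among archetypes must already satisfy the ceiling
  if (length(rows) > 1) {
    cc <- cor(t(base))
    if (any(cc[upper.tri(cc)] > max_cor)) {
      abort("archetype shapes violate the correlation ceiling; lower n_prototypes")
    }
  }
  n_extra <- n_prototypes - length(rows)
  if (n_extra > 0) {
    withr::with_seed(seed, {
      for (k in seq_len(n_extra)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          w <- cumsum(rnorm(n_time + 4))
          w <- stats::filter(w, rep(1 / 3, 3), sides = 2)
          w <- as.numeric(w[!is.na(w)])[seq_len(n_time)]
          if (pop_sd(w) == 0) next
          z <- (w - mean(w)) / pop_sd(w)
          if (all(vapply(rows, function(r) cor(r, z), numeric(1)) <= max_cor)) {
            rows[[length(rows) + 1]] <- z
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(paste0(
            "could not place prototype ", length(rows) + 1, " within ",
            max_attempts, " attempts at correlation ceiling ", max_cor
          ))
        }
      }
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("P", seq_len(n_prototypes))
  colnames(out) <- day_label(timepoints)
  out
}

#' Simulate a paired miRNA/mRNA time-course experiment
#'
#' Draws negative-binomial counts for both expression layers under a shared
#' sample design: `n_replicates` samples per (subtype, day). Regulated mRNAs
#' follow a planted prototype shape scaled by `effect_log2fc` on the log2
#' scale; each repressor miRNA follows the negated shape of its targets'
#' prototype, planting recoverable anti-correlation. Control-day samples
#' share the per-feature baseline mean (the shape is anchored at 0 there).
#' Per-sample library-size factors are drawn log-uniformly in [0.5, 2] and
#' are recorded so normalization can be audited.
#'
#' @param config a [sim_config()].
#'
#' @return A list of class `sim_experiment` with elements `mirna_counts`,
#'   `mrna_counts` (tibbles, first column `feature`), `metadata` (tibble:
#'   sample_id, subtype, day, replicate), `truth` (class `ground_truth`:
#'   `regulator_ids`, `true_pairs` tibble, `prototype_assignment` tibble,
#'   `de_features` tibble, `hub_regulator`), `prototypes`, and
#'   `true_size_factors`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  tp <- cfg$timepoints
  control_day <- tp[1]
  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("GENE-%04d", seq_len(cfg$n_mrna))

  proto <- make_prototypes(cfg$n_prototypes, tp, seed = cfg$seed)
  # anchor at the control day: shapes shift so D-1 sits exactly at baseline
  shape <- proto - proto[, 1]

  regulators <- sort(sample(mirna_ids, cfg$n_regulators))
  reg_proto <- setNames(rep_len(seq_len(cfg$n_prototypes), cfg$n_regulators),
                        regulators)

  n_targets <- cfg$n_regulators * cfg$targets_per_regulator + cfg$hub_bonus_targets
  target_pool <- sample(mrna_ids, n_targets)
  sizes <- rep(cfg$targets_per_regulator, cfg$n_regulators)
  sizes[1] <- sizes[1] + cfg$hub_bonus_targets
  target_split <- split(target_pool, rep(seq_len(cfg$n_regulators), times = sizes))

  true_pairs <- tibble(
    mirna = rep(regulators, times = sizes),
    mrna = unlist(target_split, use.names = FALSE)
  )
  proto_assign <- tibble(
    feature = true_pairs$mrna,
    prototype = reg_proto[true_pairs$mirna]
  ) %>% distinct()

  hub_regulator <- regulators[which.max(sizes)]

  metadata <- tidyr::expand_grid(
    subtype = cfg$subtypes, day = tp, replicate = seq_len(cfg$n_replicates)
  ) %>%
    mutate(sample_id = paste0(.data$subtype, "_", day_label(.data$day),
                              "_r", .data$replicate)) %>%
    select("sample_id", "subtype", "day", "replicate")

  n_samp <- nrow(metadata)
  # per-layer true library-size factors, log-uniform in [0.5, 2]
  sf_mirna <- exp(runif(n_samp, log(0.5), log(2)))
  sf_mrna <- exp(runif(n_samp, log(0.5), log(2)))

  base_mirna <- cfg$baseline_mean * exp(rnorm(cfg$n_mirna, 0, cfg$baseline_sdlog))
  base_mrna <- cfg$baseline_mean * exp(rnorm(cfg$n_mrna, 0, cfg$baseline_sdlog))
  names(base_mirna) <- mirna_ids
  names(base_mrna) <- mrna_ids

  # per-feature shape index: 0 = flat (null feature)
  shape_of <- function(ids) {
    s <- setNames(integer(length(ids)), ids)
    s[true_pairs$mrna[true_pairs$mrna %in% ids]] <-
      proto_assign$prototype[match(true_pairs$mrna[true_pairs$mrna %in% ids],
                                   proto_assign$feature)]
    s[names(reg_proto)[names(reg_proto) %in% ids]] <-
      -reg_proto[names(reg_proto) %in% ids]  # negative index = negated shape
    s
  }
  shp_mirna <- shape_of(mirna_ids)
  shp_mrna <- shape_of(mrna_ids)

  mean_matrix <- function(base, shp) {
    # features x timepoints expected counts (before size factors)
    mm <- matrix(base, nrow = length(base), ncol = length(tp))
    idx <- which(shp != 0)
    if (length(idx) > 0 && cfg$effect_log2fc != 0) {
      sgn <- sign(shp[idx])
      mm[idx, ] <- base[idx] *
        2^(cfg$effect_log2fc * sgn * shape[abs(shp[idx]), , drop = FALSE])
    }
    rownames(mm) <- names(base)
    colnames(mm) <- day_label(tp)
    mm
  }
  mu_mirna <- mean_matrix(base_mirna, shp_mirna)
  mu_mrna <- mean_matrix(base_mrna, shp_mrna)

  draw_counts <- function(mu, sf) {
    day_col <- match(day_label(metadata$day), colnames(mu))
    m <- vapply(seq_len(n_samp), function(j) {
      rnbinom(nrow(mu), mu = sf[j] * mu[, day_col[j]], size = 1 / cfg$dispersion)
    }, numeric(nrow(mu)))
    colnames(m) <- metadata$sample_id
    rownames(m) <- rownames(mu)
    m
  }
  mirna_counts <- matrix_to_tibble(draw_counts(mu_mirna, sf_mirna))
  mrna_counts <- matrix_to_tibble(draw_counts(mu_mrna, sf_mrna))

  de_features <- if (cfg$effect_log2fc == 0) {
    tibble(subtype = character(), day = numeric(), feature = character())
  } else {
    affected <- c(names(shp_mirna)[shp_mirna != 0], names(shp_mrna)[shp_mrna != 0])
    tidyr::expand_grid(subtype = cfg$subtypes, day = tp[-1], feature = affected)
  }

  truth <- structure(list(
    regulator_ids = regulators,
    true_pairs = true_pairs,
    prototype_assignment = proto_assign,
    de_features = de_features,
    hub_regulator = hub_regulator
  ), class = "ground_truth")

  structure(list(
    mirna_counts = mirna_counts,
    mrna_counts = mrna_counts,
    metadata = metadata,
    truth = truth,
    prototypes = proto,
    true_size_factors = tibble(
      sample_id = metadata$sample_id,
      mirna = sf_mirna, mrna = sf_mrna
    ),
    config = cfg
  ), class = "sim_experiment")
}

#' Simulate a multi-source miRNA-target annotation table
#'
#' Emulates the output of a multi-database target-annotation query: every
#' planted true pair receives at least one predicted record (score percentile
#' drawn in `(0, true_max_percentile]`, since genuine targets rank near the
#' top of each database); a configurable fraction gains support from two or
#' more distinct predicted sources, and another fraction a validated record.
#' Decoy records — pairs absent from the ground truth, with percentiles
#' uniform in (0, 100] — are mixed in so that `decoy_fraction` of all records
#' are decoys. The first three sources are validated-evidence databases, the
#' remainder prediction databases.
#'
#' @param truth a `ground_truth` object from [simulate_experiment()].
#' @param config the matching [sim_config()].
#'
#' @return An interaction tibble with columns `mirna`, `target`, `source`,
#'   `evidence` ("validated"/"predicted") and `score_percentile` (NA for
#'   validated records).
#' @export
simulate_annotation <- function(truth, config = sim_config()) {
  validate_sim_config(config)
  if (nrow(truth$true_pairs) == 0) abort("ground truth has no true pairs")
  withr::with_seed(config$seed + 1L, simulate_annotation_impl(truth, config))
}

simulate_annotation_impl <- function(truth, cfg) {
  sources <- sprintf("srcdb%02d", seq_len(cfg$n_sources))
  n_val_src <- min(3, cfg$n_sources)
  val_sources <- sources[seq_len(n_val_src)]
  pred_sources <- if (cfg$n_sources > n_val_src) sources[-seq_len(n_val_src)] else sources

  tp <- truth$true_pairs
  n_true <- nrow(tp)

  multi <- runif(n_true) < cfg$frac_multi_source
  n_pred_src <- ifelse(multi, pmin(sample(2:4, n_true, replace = TRUE),
                                   length(pred_sources)), 1L)
  pred_rec <- purrr::map_dfr(seq_len(n_true), function(i) {
    src <- sample(pred_sources, n_pred_src[i])
    tibble(
      mirna = tp$mirna[i], target = tp$mrna[i], source = src,
      evidence = "predicted",
      score_percentile = runif(length(src), 0, cfg$true_max_percentile)
    )
  })
  has_val <- runif(n_true) < cfg$frac_validated
  val_rec <- tibble(
    mirna = tp$mirna[has_val], target = tp$mrna[has_val],
    source = sample(val_sources, sum(has_val), replace = TRUE),
    evidence = "validated", score_percentile = NA_real_
  )
  true_rec <- bind_rows(pred_rec, val_rec)

  n_decoy <- round(cfg$decoy_fraction / (1 - cfg$decoy_fraction) * nrow(true_rec))
  decoy_rec <- NULL
  if (n_decoy > 0) {
    mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
    mrna_ids <- sprintf("GENE-%04d", seq_len(cfg$n_mrna))
    true_key <- paste(tp$mirna, tp$mrna)
    cand <- tibble(
      mirna = sample(mirna_ids, 2 * n_decoy, replace = TRUE),
      target = sample(mrna_ids, 2 * n_decoy, replace = TRUE)
    ) %>%
      filter(!paste(.data$mirna, .data$target) %in% true_key) %>%
      distinct() %>%
      head(n_decoy)
    decoy_rec <- cand %>%
      mutate(
        source = sample(pred_sources, nrow(cand), replace = TRUE),
        evidence = "predicted",
        score_percentile = runif(nrow(cand), 0, 100)
      )
  }

  bind_rows(true_rec, decoy_rec) %>%
    distinct(.data$mirna, .data$target, .data$source, .keep_all = TRUE) %>%
    arrange(.data$mirna, .data$target, .data$source)
}

#' Simulate gene-set collections for over-representation analysis
#'
#' Builds a small GMT-style collection over the simulated mRNA universe: a
#' few sets concentrated within planted prototype groups (signal) plus random
#' background sets.
#'
#' @param truth `ground_truth` object.
#' @param config the matching [sim_config()].
#' @param n_random number of random background sets.
#' @param set_size size of each random set.
#'
#' @return A tibble with columns `set_id`, `description`, `members`
#'   (list-column of character vectors), as returned by [read_gmt()].
#' @export
simulate_gene_sets <- function(truth, config = sim_config(), n_random = 10,
                               set_size = 50) {
  withr::with_seed(config$seed + 2L, {
    mrna_ids <- sprintf("GENE-%04d", seq_len(config$n_mrna))
    pa <- truth$prototype_assignment
    proto_sets <- pa %>%
      group_by(.data$prototype) %>%
      summarise(members = list(sort(.data$feature)), .groups = "drop") %>%
      mutate(
        set_id = paste0("PROTO_SET_", .data$prototype),
        description = "genes of one planted temporal prototype"
      ) %>%
      select("set_id", "description", "members")
    rand_sets <- tibble(
      set_id = sprintf("RANDOM_SET_%02d", seq_len(n_random)),
      description = "random background set",
      members = purrr::map(seq_len(n_random),
                           function(i) sort(sample(mrna_ids, set_size)))
    )
    bind_rows(proto_sets, rand_sets)
  })
}
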