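test_that("prototype shapes are z-scaled, decorrelated, and reproducible", {
  # single shape is valid
  p1 <- make_prototypes(1, seed = 1)
  expect_equal(dim(p1), c(1, 9))

  p2 <- make_prototypes(2, seed = 7)
  expect_equal(rowMeans(p2), c(P1 = 0, P2 = 0), tolerance = 1e-9)
  expect_equal(apply(p2, 1, function(r) sqrt(mean((r - mean(r))^2))),
               c(P1 = 1, P2 = 1), tolerance = 1e-9)

  # default grid, 8 shapes: pairwise correlation ceiling checked directly
  p8 <- make_prototypes(8, seed = 3)
  expect_equal(dim(p8), c(8, 9))
  cc <- cor(t(p8))
  expect_true(all(cc[upper.tri(cc)] <= 0.7 + 1e-12))

  # shapes beyond the archetype bank are random but still bounded
  p12 <- make_prototypes(12, seed = 5)
  cc12 <- cor(t(p12))
  expect_true(all(cc12[upper.tri(cc12)] <= 0.7 + 1e-12))

  expect_identical(make_prototypes(8, seed = 3), p8)
  # required archetypes present: monotone up/down, early peak/trough at the
  # first post-control position
  expect_true(all(diff(p8[1, ]) > 0))
  expect_true(all(diff(p8[2, ]) < 0))
  expect_equal(unname(which.max(p8[3, ])), 2)
  expect_equal(unname(which.min(p8[4, ])), 2)
})

test_that("simulated experiments honor the planted design and reproduce exactly", {
  cfg <- sim_config(n_mirna = 30, n_mrna = 200, n_regulators = 5,
                    targets_per_regulator = 8, hub_bonus_targets = 4,
                    seed = 11)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$mirna_counts), 30)
  expect_equal(nrow(sim$mrna_counts), 200)
  # duplicate samples at 9 time points in each of two subtypes
  expect_equal(nrow(sim$metadata), 2 * 9 * 2)
  m <- as.matrix(sim$mrna_counts[, -1])
  expect_true(all(m >= 0) && all(m == round(m)))

  # planted-pair arithmetic
  expect_equal(nrow(sim$truth$true_pairs), 5 * 8 + 4)
  expect_true(all(sim$truth$true_pairs$mirna %in% sim$truth$regulator_ids))
  counts_per_reg <- table(sim$truth$true_pairs$mirna)
  expect_equal(unname(sort(counts_per_reg, decreasing = TRUE)[1]), 12)
  expect_identical(sim$truth$hub_regulator,
                   names(which.max(counts_per_reg)))

  # the symmetric design used in the target-count contract
  cfg600 <- sim_config(hub_bonus_targets = 0, seed = 2)
  sim600 <- simulate_experiment(cfg600)
  expect_equal(nrow(sim600$truth$true_pairs), 20 * 30)

  # identical seeds give byte-identical serialized outputs
  sim2 <- simulate_experiment(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$mrna_counts, f1)
  write_counts(sim2$mrna_counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a null simulation plants nothing", {
  cfg <- sim_config(n_mirna = 20, n_mrna = 100, n_regulators = 3,
                    targets_per_regulator = 5, hub_bonus_targets = 0,
                    effect_log2fc = 0, seed = 4)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth$de_features), 0)
})

test_that("control-day means sit at baseline and planted shapes modulate the rest", {
  # near-noiseless simulation: regulated means must track the prototype and
  # control day must stay at baseline for every feature
  cfg <- sim_config(n_mirna = 20, n_mrna = 120, n_regulators = 4,
                    targets_per_regulator = 10, hub_bonus_targets = 0,
                    dispersion = 1e-3, baseline_sdlog = 0, seed = 9)
  sim <- simulate_experiment(cfg)
  sf <- sim$true_size_factors
  m <- as.matrix(sim$mrna_counts[, -1])
  rownames(m) <- sim$mrna_counts$feature
  norm <- sweep(m, 2, sf$mrna, "/")
  ctrl <- sim$metadata$sample_id[sim$metadata$day == -1]
  ctrl_means <- rowMeans(norm[, ctrl])
  expect_equal(unname(ctrl_means), rep(cfg$baseline_mean, 120),
               tolerance = 0.1)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_regulators = 200), "n_regulators")
  expect_error(sim_config(n_mrna = 100, n_regulators = 20,
                          targets_per_regulator = 30), "exceed")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_replicates = 1), "replicates")
  expect_error(sim_config(timepoints = c(0, 0, 1)), "increasing")
})

test_that("null feature variance follows mu + alpha * mu^2", {
  cfg <- sim_config(n_mirna = 20, n_mrna = 1200, n_regulators = 2,
                    targets_per_regulator = 5, hub_bonus_targets = 0,
                    effect_log2fc = 0, n_replicates = 6,
                    subtypes = "PMD", timepoints = c(-1, 0),
                    n_prototypes = 2, dispersion = 0.1, seed = 21)
  sim <- simulate_experiment(cfg)
  m <- as.matrix(sim$mrna_counts[, -1])
  rownames(m) <- sim$mrna_counts$feature
  grp <- sim$metadata$sample_id[sim$metadata$day == 0]
  sf <- sim$true_size_factors$mrna[match(grp, sim$true_size_factors$sample_id)]
  x <- m[, grp]
  # expected within-group sample variance accounts for the per-sample
  # library factors: E[s^2] = mean_j(v_j) + sum_j (m_j - mbar)^2 / (J - 1)
  # with m_j = sf_j * mu_i and v_j = m_j + alpha * m_j^2
  base <- rowMeans(sweep(x, 2, sf, "/"))
  mj <- outer(base, sf)
  vj <- mj + cfg$dispersion * mj^2
  expected <- rowMeans(vj) +
    rowSums((mj - rowMeans(mj))^2) / (length(grp) - 1)
  observed <- apply(x, 1, var)
  expect_equal(mean(observed) / mean(expected), 1, tolerance = 0.05)
})

test_that("planted regulator/target profiles anti-correlate at low noise", {
  # large baseline and tiny dispersion so both NB and Poisson-level noise
  # are negligible relative to the planted shape spacing
  cfg <- sim_config(n_mirna = 20, n_mrna = 120, n_regulators = 4,
                    targets_per_regulator = 10, hub_bonus_targets = 0,
                    dispersion = 1e-4, baseline_mean = 1e6,
                    baseline_sdlog = 0, seed = 13)
  sim <- simulate_experiment(cfg)
  sf_mi <- estimate_size_factors(sim$mirna_counts)
  sf_mr <- estimate_size_factors(sim$mrna_counts)
  prof_mi <- time_profiles(normalize_counts(sim$mirna_counts, sf_mi),
                           sim$metadata, "PMD")
  prof_mr <- time_profiles(normalize_counts(sim$mrna_counts, sf_mr),
                           sim$metadata, "PMD")
  mi <- as.matrix(prof_mi[, -1]); rownames(mi) <- prof_mi$feature
  mr <- as.matrix(prof_mr[, -1]); rownames(mr) <- prof_mr$feature
  rhos <- vapply(seq_len(nrow(sim$truth$true_pairs)), function(i) {
    spearman_rho(mi[sim$truth$true_pairs$mirna[i], ],
                 mr[sim$truth$true_pairs$mrna[i], ])
  }, numeric(1))
  expect_true(mean(rhos) < -0.95)
  expect_true(all(rhos < -0.7))
})

test_that("annotation tables contain every true pair plus controlled decoys", {
  cfg <- sim_config(n_mirna = 30, n_mrna = 200, n_regulators = 5,
                    targets_per_regulator = 10, hub_bonus_targets = 0,
                    seed = 17)
  sim <- simulate_experiment(cfg)
  ann <- simulate_annotation(sim$truth, cfg)
  key_true <- paste(sim$truth$true_pairs$mirna, sim$truth$true_pairs$mrna)
  key_ann <- unique(paste(ann$mirna, ann$target))
  expect_true(all(key_true %in% key_ann))
  expect_true(all(ann$evidence %in% c("validated", "predicted")))
  pred <- ann[ann$evidence == "predicted", ]
  expect_true(all(pred$score_percentile > 0 & pred$score_percentile <= 100))
  expect_setequal(unique(ann$source), sprintf("srcdb%02d", 1:14))

  # decoy_fraction = 0: every record is a true pair
  cfg0 <- sim_config(n_mirna = 30, n_mrna = 200, n_regulators = 5,
                     targets_per_regulator = 10, hub_bonus_targets = 0,
                     decoy_fraction = 0, seed = 17)
  ann0 <- simulate_annotation(sim$truth, cfg0)
  expect_true(all(paste(ann0$mirna, ann0$target) %in% key_true))

  # a validated-only pair survives the support filter
  one <- tibble::tibble(mirna = "miR-900", target = "GENE-X",
                        source = "srcdb01", evidence = "validated",
                        score_percentile = NA_real_)
  expect_equal(nrow(support_filter(one)), 1)
})
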