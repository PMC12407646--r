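test_that("median-of-ratios size factors match hand-derived values", {
  # identical samples
  sf <- estimate_size_factors(counts_tbl(cbind(c(5, 8, 2), c(5, 8, 2))))
  expect_equal(sf$size_factor, c(1, 1))

  # elementwise doubling: ratio of factors is 2
  sf2 <- estimate_size_factors(counts_tbl(cbind(c(5, 8, 2), 2 * c(5, 8, 2))))
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1], 2)

  # hand-computed median of per-feature ratios, rescaled to geometric mean 1
  sf3 <- estimate_size_factors(
    counts_tbl(matrix(c(10, 20, 100, 200, 5, 10), nrow = 3, byrow = TRUE))
  )
  expect_equal(sf3$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # all-zero-free reference required
  expect_error(
    estimate_size_factors(counts_tbl(matrix(c(0, 5, 3, 0), 2))),
    "reference"
  )
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(600 * 8, mu = 150, size = 10), 600)
  m <- sweep(m, 2, exp(runif(8, log(0.5), log(2))), function(a, b) round(a * b))
  ours <- estimate_size_factors(counts_tbl(m))$size_factor
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(ours, unname(ref), tolerance = 1e-8)
})

test_that("normalization divides by factors and equalizes reference medians", {
  counts <- counts_tbl(matrix(c(10, 20, 100, 200, 5, 10), nrow = 3,
                              byrow = TRUE))
  sf1 <- tibble::tibble(sample_id = c("s01", "s02"), size_factor = c(1, 1))
  expect_equal(as.matrix(normalize_counts(counts, sf1)[, -1]),
               as.matrix(counts[, -1]))
  sf2 <- tibble::tibble(sample_id = c("s01", "s02"), size_factor = c(2, 1))
  expect_equal(normalize_counts(counts, sf2)[[2]], c(5, 50, 2.5))

  # after median-of-ratios, the per-sample median ratio to the reference is 1
  set.seed(1)
  m <- matrix(rnbinom(301 * 5, mu = 100, size = 5) + 1, 301)
  tbl <- counts_tbl(m)
  sf <- estimate_size_factors(tbl)
  norm <- as.matrix(normalize_counts(tbl, sf)[, -1])
  geo <- exp(rowMeans(log(m)))
  med_ratio <- apply(sweep(norm, 1, geo, "/"), 2, median)
  expect_equal(unname(med_ratio / med_ratio[1]), rep(1, 5), tolerance = 1e-9)
})

test_that("the Wald contrast handles symmetric, all-zero, and degenerate input", {
  m <- rbind(
    same = c(10, 12, 10, 12),       # identical counts in both groups
    zero = c(0, 0, 0, 0),           # never observed
    up = c(100, 110, 10, 12)
  )
  counts <- counts_tbl(m, samples = paste0("s", 1:4))
  md <- two_group_metadata(paste0("s", 1:4))
  sf <- tibble::tibble(sample_id = paste0("s", 1:4), size_factor = rep(1, 4))
  ct <- nb_wald_contrast(counts, md, "PMD", 1, size_factors = sf)

  expect_equal(ct$log2fc[ct$feature == "same"], 0)
  expect_equal(ct$wald_p[ct$feature == "same"], 1, tolerance = 1e-9)
  expect_equal(ct$status[ct$feature == "zero"], "all-zero")
  expect_true(is.na(ct$wald_p[ct$feature == "zero"]))
  expect_true(ct$log2fc[ct$feature == "up"] > 2)

  # p-values are defined exactly for tested features
  expect_identical(is.na(ct$wald_p), ct$status == "all-zero")

  expect_error(nb_wald_contrast(counts, md, "PMD", 99), "not found")
  expect_error(nb_wald_contrast(counts, md, "DDR", 1), "not found")
})

test_that("Wald p-values are monotone in |log2FC| at fixed standard error", {
  set.seed(5)
  m <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200)
  counts <- counts_tbl(m, samples = paste0("s", 1:4))
  md <- two_group_metadata(paste0("s", 1:4))
  ct <- nb_wald_contrast(counts, md, "PMD", 1)
  ct <- ct[ct$status == "tested", ]
  # the reported p is exactly the two-sided normal tail of log2fc/se, hence
  # monotone decreasing in the |z| ordering
  expect_equal(ct$wald_p, 2 * pnorm(-abs(ct$log2fc / ct$se)))
  o <- order(abs(ct$log2fc / ct$se))
  expect_true(all(diff(ct$wald_p[o]) <= 1e-12))
})

test_that("DE calling applies strict thresholds and round-trips", {
  ct <- tibble::tibble(
    feature = c("a", "b", "c", "d", "e"),
    base_mean = 100, se = 0.3,
    log2fc = c(1.2, 1.0, 3.0, -1.4, -0.9),
    wald_p = c(0.04, 0.04, 0.05, 0.01, 0.001),
    p_adj = NA_real_, status = "tested",
    subtype = "PMD", day = 1
  )
  de <- call_de(ct)
  expect_identical(de$feature[de$direction == "up"], "a")     # p<.05 & lfc>1
  expect_identical(de$feature[de$direction == "down"], "d")
  # b: lfc exactly 1 excluded; c: p exactly .05 excluded; e: |lfc| < 1
  expect_false(any(c("b", "c", "e") %in% de$feature))

  # members re-verify their thresholds against the contrast table
  audit <- merge(de, ct)
  expect_true(all(audit$wald_p < 0.05 & abs(audit$log2fc) > 1))
})

test_that("sample PCA matches an eigendecomposition oracle", {
  set.seed(8)
  m <- matrix(rexp(5 * 4, 1 / 50), nrow = 5)
  norm <- counts_tbl(m)
  pca <- pca_profiles(norm, n_components = 2)

  x <- t(log10(m + 1))
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(xc))
  oracle_scores <- xc %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    got <- pca$scores[[paste0("PC", j)]]
    expect_true(max(abs(got - oracle_scores[, j])) < 1e-9 ||
                  max(abs(got + oracle_scores[, j])) < 1e-9)
  }
  expect_equal(pca$var_explained[1:2],
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-9)
  expect_true(all(diff(pca$var_explained) <= 1e-12))

  # duplicated samples land on identical coordinates
  m2 <- cbind(m, m[, 4])
  pca2 <- pca_profiles(counts_tbl(m2))
  expect_equal(unlist(pca2$scores[4, -1]), unlist(pca2$scores[5, -1]))

  # a rank-1 signal puts all variance on PC1
  pca3 <- pca_profiles(counts_tbl(outer(rep(1, 6), c(1, 10, 100, 1000))))
  expect_equal(pca3$var_explained[1], 1, tolerance = 1e-9)

  expect_error(pca_profiles(counts_tbl(matrix(5, 3, 3))), "constant")
})
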