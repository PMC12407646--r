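test_that("profile standardization z-scales rows and drops flat profiles", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1) / sqrt(2 / 3))
  prof <- profile_tbl(m, days = c(-1, 0, 1))
  expect_message(z <- standardize_profiles(prof), "constant")
  expect_identical(z$feature, c("a", "c"))
  expect_identical(attr(z, "dropped"), "b")
  # population-sd z-score of (1,2,3)
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1.22474487139159, 0, 1.22474487139159), tolerance = 1e-9)
  # idempotence on an already standardized row
  expect_equal(unlist(z[2, -1], use.names = FALSE),
               unlist(standardize_profiles(z)[2, -1], use.names = FALSE),
               tolerance = 1e-9)
  expect_error(standardize_profiles(profile_tbl(matrix(1, 2, 3))), "constant")
})

test_that("the fuzzifier heuristic matches its formula and limits", {
  prof <- profile_tbl(matrix(rnorm(500 * 9), 500),
                      features = sprintf("g%03d", 1:500))
  m <- estimate_fuzzifier(prof)
  # independent transcription of the heuristic at N = 500, D = 9
  N <- 500; D <- 9
  expect_equal(
    m,
    1 + (1418 / N + 22.05) * D^(-2) +
      (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134),
    tolerance = 1e-12
  )
  expect_gt(m, 1)
  # m decreases with N toward the D-only terms
  big <- profile_tbl(matrix(rnorm(5000 * 9), 5000),
                     features = sprintf("g%04d", 1:5000))
  expect_lt(estimate_fuzzifier(big), m)
})

test_that("fuzzy c-means degenerates correctly and keeps its invariants", {
  # two point masses: centroids land on the masses, memberships saturate
  base <- rbind(c(1, 0, -1), c(-1, 0, 1)) / sqrt(2 / 3)
  x <- base[rep(1:2, each = 5), ]
  prof <- profile_tbl(x, days = 0:2, features = sprintf("f%02d", 1:10))
  fit <- fuzzy_cmeans(prof, c = 2, m = 1.5, seed = 1)
  expect_true(fit$converged)
  ord <- if (cor(fit$centroids[1, ], base[1, ]) > 0) 1:2 else 2:1
  expect_equal(unname(fit$centroids[ord, ]), unname(base), tolerance = 1e-4)
  top <- apply(fit$membership, 1, max)
  expect_true(all(top > 0.99))

  # c = 1: centroid is the mean profile, memberships all 1
  fit1 <- fuzzy_cmeans(prof, c = 1, m = 2, seed = 1)
  expect_equal(unname(fit1$centroids[1, ]), unname(colMeans(x)),
               tolerance = 1e-6)
  expect_equal(unname(fit1$membership[, 1]), rep(1, 10))

  # invariants: membership rows sum to 1, objective never increases,
  # identical seeds reproduce the model
  set.seed(3)
  noisy <- x + matrix(rnorm(30, sd = 0.3), 10)
  prof2 <- standardize_profiles(profile_tbl(noisy, days = 0:2,
                                            features = sprintf("f%02d", 1:10)))
  fit2 <- fuzzy_cmeans(prof2, c = 2, m = 1.8, seed = 5)
  expect_equal(unname(rowSums(fit2$membership)), rep(1, nrow(prof2)),
               tolerance = 1e-9)
  expect_true(all(diff(fit2$objective_trace) <= 1e-10))
  expect_identical(fuzzy_cmeans(prof2, c = 2, m = 1.8, seed = 5)$membership,
                   fit2$membership)
  expect_error(fuzzy_cmeans(prof2, c = 20, m = 2), "fewer features")
})

test_that("cluster labels are arbitrary: relabeling leaves core partitions intact", {
  set.seed(11)
  proto <- make_prototypes(3, seed = 2)
  x <- proto[rep(1:3, each = 30), ] + matrix(rnorm(90 * 9, sd = 0.3), 90)
  prof <- standardize_profiles(profile_tbl(x, days = c(-1, 0, 1, 2, 3, 4, 6, 8, 16),
                                           features = sprintf("f%03d", 1:90)))
  fit_a <- fuzzy_cmeans(prof, c = 3, m = 1.6, seed = 1)
  fit_b <- fuzzy_cmeans(prof, c = 3, m = 1.6, seed = 99)
  part <- function(fit) {
    cm <- core_members(fit, 0.5)
    split(cm$feature, cm$cluster)
  }
  # same grouping up to cluster renaming: compare sorted member sets
  sets_a <- lapply(part(fit_a), sort)
  sets_b <- lapply(part(fit_b), sort)
  expect_setequal(unname(vapply(sets_a, paste, "", collapse = ",")),
                  unname(vapply(sets_b, paste, "", collapse = ",")))
})

test_that("core membership thresholding follows the argmax rule", {
  model <- structure(list(membership = rbind(
    f1 = c(0.9, 0.1), f2 = c(0.4, 0.6), f3 = c(0.45, 0.55)
  )), class = "fuzzy_cmeans")
  colnames(model$membership) <- c("C1", "C2")
  cm <- core_members(model, 0.5)
  expect_identical(cm$feature, c("f1", "f2", "f3"))
  expect_identical(cm$cluster, c("C1", "C2", "C2"))
  # a three-way split below threshold stays unassigned
  model$membership <- rbind(f1 = c(0.4, 0.35, 0.25))
  colnames(model$membership) <- paste0("C", 1:3)
  expect_equal(nrow(core_members(model, 0.5)), 0)
  # threshold 0 assigns everything
  expect_equal(nrow(core_members(model, 0)), 1)
})

test_that("planted prototypes are recovered by soft clustering", {
  skip_if_not_installed("e1071")
  proto <- make_prototypes(4, seed = 6)
  truth_lab <- rep(1:4, each = 50)
  set.seed(19)
  x <- proto[truth_lab, ] + matrix(rnorm(200 * 9, sd = 0.3), 200)
  prof <- standardize_profiles(profile_tbl(x, days = c(-1, 0, 1, 2, 3, 4, 6, 8, 16),
                                           features = sprintf("g%03d", 1:200)))
  fit <- fuzzy_cmeans(prof, c = 4, m = 1.5, seed = 2)
  hard <- apply(fit$membership, 1, which.max)
  expect_gte(oracle_ari(hard, truth_lab), 0.9)

  # an established fuzzy c-means implementation agrees on the centroids
  ref <- e1071::cmeans(as.matrix(prof[, -1]), centers = fit$centroids,
                       m = 1.5, iter.max = 200)
  agree <- cor(t(fit$centroids), t(ref$centers))
  expect_true(all(apply(agree, 1, max) > 0.99))
})

test_that("the cluster-count scan flags redundant centroid pairs", {
  days <- c(-1, 0, 1, 2, 3, 4, 6, 8, 16)
  # one planted shape: asking for 2 clusters forces near-duplicate centroids
  proto1 <- make_prototypes(1, seed = 4)
  set.seed(2)
  x1 <- proto1[rep(1, 80), ] + matrix(rnorm(80 * 9, sd = 0.2), 80)
  prof1 <- standardize_profiles(profile_tbl(x1, days = days,
                                            features = sprintf("g%03d", 1:80)))
  scan1 <- scan_cluster_count(prof1, c_range = 2, m = 1.5, seed = 3)
  expect_true(scan1$redundant[scan1$c == 2])
  # two well-separated shapes: 2 clusters are not redundant
  proto2 <- make_prototypes(2, seed = 4)
  x2 <- proto2[rep(1:2, each = 40), ] + matrix(rnorm(80 * 9, sd = 0.2), 80)
  prof2 <- standardize_profiles(profile_tbl(x2, days = days,
                                            features = sprintf("h%03d", 1:80)))
  scan2 <- scan_cluster_count(prof2, c_range = 2, m = 1.5, seed = 3)
  expect_false(scan2$redundant[scan2$c == 2])
})
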