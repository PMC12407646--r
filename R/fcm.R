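#' Fuzzy c-means soft clustering of temporal profiles
#'
#' Soft-clusters standardized temporal profiles with the fuzzy c-means
#' alternating scheme: memberships
#' `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))` with Euclidean distances to the
#' current centroids, then weighted centroids
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`. A feature sitting exactly on a
#' centroid gets membership 1 for that cluster. Centroids are seeded
#' kmeans++-style from the data rows under the supplied seed. Iteration
#' stops when the largest centroid displacement falls below `tol`; hitting
#' `max_iter` first returns the model flagged unconverged rather than
#' erroring. The objective `sum_ik u_ik^m d_ik^2` is recorded every
#' iteration and is non-increasing.
#'
#' @param profiles standardized profile tibble ([standardize_profiles()]).
#' @param c number of clusters (>= 1; must not exceed the feature count).
#' @param m fuzzifier (> 1); default from [estimate_fuzzifier()].
#' @param seed integer seed for centroid seeding.
#' @param tol convergence tolerance on centroid displacement.
#' @param max_iter iteration cap.
#' @param nstart number of independent seedings; the fit with the lowest
#'   final objective is returned (start seeds derive deterministically from
#'   `seed`).
#'
#' @return object of class `fuzzy_cmeans`: list with `centroids` (c x D
#'   matrix), `membership` (N x c matrix, rows sum to 1), `m`, `c`,
#'   `objective_trace`, `iterations`, `converged`, `features`,
#'   `timepoints`.
#' @export
fuzzy_cmeans <- function(profiles, c, m = NULL, seed = 1, tol = 1e-6,
                         max_iter = 1000, nstart = 5) {
  x <- profile_matrix(profiles)
  n <- nrow(x)
  if (c < 1) abort("c must be >= 1")
  if (n < c) abort("fewer features than clusters")
  if (is.null(m)) m <- estimate_fuzzifier(profiles)
  if (m <= 1) abort("fuzzifier m must exceed 1")

  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- fcm_single(x, c, m, seed + 7919L * (s - 1L), tol, max_iter)
    if (is.null(best) ||
        utils::tail(fit$objective_trace, 1) <
          utils::tail(best$objective_trace, 1)) {
      best <- fit
    }
  }
  structure(c(best, list(
    m = m, c = c, features = rownames(x),
    timepoints = attr(profiles, "timepoints")
  )), class = "fuzzy_cmeans")
}

fcm_single <- function(x, c, m, seed, tol, max_iter) {
  centroids <- withr::with_seed(seed, seed_kmeanspp(x, c))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  membership <- NULL
  repeat {
    iter <- iter + 1
    d2 <- dist2_to_centroids(x, centroids)
    membership <- fcm_membership(d2, m)
    trace <- c(trace, sum(membership^m * d2))
    um <- membership^m
    new_centroids <- crossprod(um, x) / colSums(um)
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  dimnames(centroids) <- list(paste0("C", seq_len(c)), colnames(x))
  dimnames(membership) <- list(rownames(x), paste0("C", seq_len(c)))
  list(centroids = centroids, membership = membership,
       objective_trace = trace, iterations = iter, converged = converged)
}

# kmeans++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre. Operates on the current RNG state.
seed_kmeanspp <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (k in seq_len(c - 1)) {
    d2 <- dist2_to_centroids(x, x[idx, , drop = FALSE])
    mind2 <- apply(d2, 1, min)
    mind2[idx] <- 0
    if (sum(mind2) == 0) {
      cand <- setdiff(seq_len(n), idx)
      idx <- c(idx, cand[sample.int(length(cand), 1)])
    } else {
      idx <- c(idx, sample.int(n, 1, prob = mind2 / sum(mind2)))
    }
  }
  x[idx, , drop = FALSE]
}

# squared Euclidean distances, N x c
dist2_to_centroids <- function(x, centroids) {
  xx <- rowSums(x^2)
  cc <- rowSums(centroids^2)
  d2 <- outer(xx, cc, "+") - 2 * tcrossprod(x, centroids)
  pmax(d2, 0)
}

fcm_membership <- function(d2, m) {
  pow <- -1 / (m - 1)
  w <- d2^pow                                # (d^2)^(-1/(m-1)) = d^(-2/(m-1))
  u <- w / rowSums(w)
  # exact hits (d = 0) and numerically overflowing rows: membership 1 for
  # the nearest centroid
  bad <- rowSums(d2 <= .Machine$double.eps) > 0 | !is.finite(rowSums(u))
  if (any(bad)) {
    rows <- which(bad)
    nearest <- apply(d2[rows, , drop = FALSE], 1, which.min)
    u[rows, ] <- 0
    u[cbind(rows, nearest)] <- 1
  }
  u
}

#' Core cluster members by membership threshold
#'
#' Assigns each feature to its argmax cluster when the maximal membership
#' reaches `min_membership`; features below the threshold stay unassigned.
#'
#' @param model fitted [fuzzy_cmeans()] model.
#' @param min_membership membership threshold in [0, 1].
#' @return tibble with columns feature, cluster (e.g. "C1"), membership —
#'   assigned features only.
#' @export
core_members <- function(model, min_membership = 0.5) {
  u <- model$membership
  best <- max.col(u, ties.method = "first")
  mm <- u[cbind(seq_len(nrow(u)), best)]
  keep <- mm >= min_membership
  tibble(
    feature = rownames(u)[keep],
    cluster = colnames(u)[best[keep]],
    membership = mm[keep]
  )
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat("fuzzy c-means:", length(x$features), "features,", x$c,
      "clusters, m =", signif(x$m, 4), "\n")
  cat(x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      "- objective", signif(utils::tail(x$objective_trace, 1), 6), "\n")
  invisible(x)
}

#' Tidy a fuzzy c-means model
#'
#' @param x fitted `fuzzy_cmeans` model.
#' @param ... unused.
#' @return long tibble: feature, cluster, membership.
#' @method tidy fuzzy_cmeans
#' @export
tidy.fuzzy_cmeans <- function(x, ...) {
  as_tibble(x$membership, rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "cluster",
                        values_to = "membership")
}

#' @rdname tidy.fuzzy_cmeans
#' @return `glance()`: one-row tibble with c, m, n_features, iterations,
#'   converged, objective.
#' @method glance fuzzy_cmeans
#' @export
glance.fuzzy_cmeans <- function(x, ...) {
  tibble(
    c = x$c, m = x$m, n_features = length(x$features),
    iterations = x$iterations, converged = x$converged,
    objective = utils::tail(x$objective_trace, 1)
  )
}

#' Scan cluster counts by centroid redundancy
#'
#' Fits fuzzy c-means over a range of cluster counts and flags counts where
#' any two centroids correlate above `max_centroid_cor` (redundant
#' clusters). The largest non-redundant count is suggested.
#'
#' @param profiles standardized profiles.
#' @param c_range candidate cluster counts.
#' @param cor_ceiling redundancy ceiling on pairwise centroid Pearson
#'   correlation.
#' @param ... passed to [fuzzy_cmeans()].
#' @return tibble: c, max_centroid_cor, redundant, with the suggestion in
#'   the `suggested_c` attribute.
#' @export
scan_cluster_count <- function(profiles, c_range = 2:10,
                               cor_ceiling = 0.85, ...) {
  res <- purrr::map_dfr(c_range, function(cc) {
    fit <- fuzzy_cmeans(profiles, c = cc, ...)
    mc <- if (cc < 2) -1 else {
      ctr <- cor(t(fit$centroids))
      max(ctr[upper.tri(ctr)])
    }
    tibble(c = cc, max_centroid_cor = mc, redundant = mc > cor_ceiling)
  })
  ok <- res$c[!res$redundant]
  attr(res, "suggested_c") <- if (length(ok) > 0) max(ok) else min(c_range)
  res
}
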