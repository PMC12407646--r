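# Shared fixture builders and independent oracles.

# counts tibble from a plain matrix
counts_tbl <- function(m, features = NULL, samples = NULL) {
  if (is.null(features)) {
    features <- if (!is.null(rownames(m))) rownames(m) else
      sprintf("f%02d", seq_len(nrow(m)))
  }
  if (is.null(samples)) {
    samples <- if (!is.null(colnames(m))) colnames(m) else
      sprintf("s%02d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(features, samples)
  tibble::as_tibble(m, rownames = "feature")
}

# two-group single-subtype metadata for a counts matrix with samples split
# half control-day, half treatment-day
two_group_metadata <- function(samples, day = 1, control_day = -1,
                               subtype = "PMD") {
  n <- length(samples)
  half <- n %/% 2
  tibble::tibble(
    sample_id = samples,
    subtype = subtype,
    day = rep(c(day, control_day), c(half, n - half)),
    replicate = c(seq_len(half), seq_len(n - half))
  )
}

# wide profile tibble from a matrix, with timepoints attribute
profile_tbl <- function(m, days = NULL, features = NULL) {
  if (is.null(days)) days <- seq_len(ncol(m)) - 2
  if (is.null(features)) {
    features <- if (!is.null(rownames(m))) rownames(m) else
      sprintf("f%02d", seq_len(nrow(m)))
  }
  dimnames(m) <- list(features, paste0("D", days))
  out <- tibble::as_tibble(m, rownames = "feature")
  attr(out, "timepoints") <- days
  out
}

# ---- independent oracles ---------------------------------------------------

# Spearman via explicit midranks and a from-scratch Pearson formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sv <- sort(v)
    vapply(v, function(a) mean(which(sv == a)), numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Hypergeometric upper tail by direct summation of the closed-form pmf.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Adjusted Rand index between two hard labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
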