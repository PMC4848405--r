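#' Permutation p-value for a gene-set statistic
#'
#' The null model globally permutes all m x n entries of the screen matrix
#' and recomputes the statistic on the same r extracted rows. Because only
#' the extracted r x n block of a permuted matrix matters for the bimodality
#' statistic, each replicate is drawn equivalently by sampling r*n entries
#' without replacement from the pooled entries of `M` — O(r*n) per replicate
#' instead of a full shuffle. For binary matrices this collapses further to
#' exact hypergeometric sampling of per-line hit counts, which vectorizes
#' over replicates. The per-line hypergeometric product statistic also needs
#' the permuted matrix's column totals; those are drawn first from the exact
#' multivariate hypergeometric allocation of the total hit count into columns.
#'
#' The p-value uses the add-one convention p = (1 + #\{null >= obs\}) / (B + 1)
#' so that p is never zero.
#'
#' @param M a binary- or continuous-flavor [screen_matrix()].
#' @param set character vector of gene symbols.
#' @param B number of permutation replicates (default 1000).
#' @param seed integer seed; identical seeds give identical p-values.
#' @param statistic `"bimodality"` (2-means centroid gap; larger = more
#'   extreme) or `"hypergeom"` (sum of per-line log upper-tail probabilities;
#'   smaller = more extreme). The hypergeometric statistic requires binary
#'   input.
#' @param min_mapped minimum mapped set size (passed to [extract_profile()]).
#' @return list with `p` (permutation p-value), `observed` (the statistic),
#'   `null` (the B null statistics) and `r` (mapped size); or `NULL` when the
#'   set maps below `min_mapped`.
#' @export
permutation_pvalue <- function(M, set, B = 1000L, seed = NULL,
                               statistic = c("bimodality", "hypergeom"),
                               min_mapped = 3L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(M, "screen_matrix"), B >= 1L)
  ex <- extract_profile(M, set, min_mapped = min_mapped)
  if (ex$skipped) return(NULL)
  perm_pvalue_profile(M, ex$profile, B = B, seed = seed, statistic = statistic)
}

# Same, given an already-extracted profile submatrix.
perm_pvalue_profile <- function(M, P, B = 1000L, seed = NULL,
                                statistic = "bimodality") {
  r <- nrow(P); n <- ncol(P)
  if (statistic == "bimodality") {
    obs <- bimodality_score(P)
    null <- null_bimodality_scores(M, r, n, B, seed)
    p <- (1 + sum(null >= obs)) / (B + 1)
  } else {
    if (M$flavor != "binary")
      stop("the hypergeometric statistic requires a binary matrix")
    obs <- hypergeom_log_score(P, colSums(M$values), nrow(M$values))
    null <- null_hypergeom_scores(M, r, B, seed)
    p <- (1 + sum(null <= obs)) / (B + 1)
  }
  list(p = p, observed = obs, null = null, r = r)
}

# B null bimodality scores for an r x n extraction from M under the global
# permutation null.
null_bimodality_scores <- function(M, r, n, B, seed = NULL) {
  with_seed(seed, {
    if (M$flavor == "binary") {
      counts <- null_column_hit_counts(sum(M$values), nrow(M$values) * n,
                                       r, n, B)
      two_means_scores(counts / r)
    } else {
      x <- as.vector(M$values)
      vapply(seq_len(B), function(b) {
        idx <- sample.int(length(x), r * n)
        two_means_1d(colMeans(matrix(x[idx], r, n)))$score
      }, numeric(1))
    }
  })
}

# Exact multivariate-hypergeometric draw: allocate the h pooled hits of an
# mn-entry binary matrix across n sampled columns of r cells each, per
# replicate. Returns a B x n matrix of per-column hit counts among the r
# sampled rows. Conditioning column by column keeps the joint distribution
# identical to a global shuffle restricted to the sampled block.
null_column_hit_counts <- function(h, mn, r, n, B) {
  drawn <- stats::rhyper(B, h, mn - h, r * n)   # hits landing in the block
  counts <- matrix(0L, B, n)
  remaining <- drawn
  cap <- r * n
  for (j in seq_len(n - 1L)) {
    cap <- cap - r
    cj <- stats::rhyper(B, r, cap, remaining)
    counts[, j] <- cj
    remaining <- remaining - cj
  }
  counts[, n] <- remaining
  counts
}

# B null hypergeometric-product log scores. The permuted matrix's column
# totals K'_j are drawn by allocating the pooled hit count h over n columns
# of capacity m; the in-set count per column is then hypergeometric within
# the column.
null_hypergeom_scores <- function(M, r, B, seed = NULL) {
  m <- nrow(M$values); n <- ncol(M$values)
  h <- sum(M$values)
  with_seed(seed, {
    K <- matrix(0L, B, n)
    remaining <- rep.int(h, B)
    cap <- m * n
    for (j in seq_len(n - 1L)) {
      cap <- cap - m
      kj <- stats::rhyper(B, m, cap, remaining)
      K[, j] <- kj
      remaining <- remaining - kj
    }
    K[, n] <- remaining
    scores <- numeric(B)
    for (j in seq_len(n)) {
      cj <- stats::rhyper(B, K[, j], m - K[, j], r)
      scores <- scores + log_tail_p(cj, K[, j], m, r)
    }
    scores
  })
}

#' Storey q-values
#'
#' False discovery rate q-values with the null proportion pi0 estimated on a
#' lambda grid 0.05, 0.10, ..., 0.95 by cubic-smoother extrapolation of
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) at the largest lambda.
#' With `pi0 = 1` the result is exactly the Benjamini-Hochberg adjusted
#' p-values. Estimates of pi0 outside (0, 1] are clamped to 1 with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0 optional fixed null proportion; `NULL` (default) estimates it.
#' @param lambda grid for pi0 estimation.
#' @return vector of q-values, monotone nondecreasing in p, each <= 1.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  stopifnot(is.numeric(p), all(p > 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2L || stats::var(p) == 0) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
        warning("pi0 estimate ", signif(pi0, 3), " outside (0,1]; clamped to 1")
        pi0 <- 1
      }
    }
  }
  bh <- stats::p.adjust(p, method = "BH")
  pmin(pi0 * bh, 1)
}
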