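#' Column-mean sensitivity profile of a gene-set submatrix
#'
#' v_j = (1/r) * sum_i P_ij: the fraction of set members that are hits in
#' line j (for binary input), which normalizes the profile for set size.
#'
#' @param P numeric r x n profile matrix (rows = set members, columns = lines).
#' @return numeric vector of length n.
#' @export
column_mean_profile <- function(P) {
  stopifnot(is.matrix(P), nrow(P) >= 1L)
  colMeans(P)
}

#' Exact 1-D 2-means clustering
#'
#' Globally optimal two-cluster partition of a numeric vector, minimizing the
#' within-cluster sum of squares. In one dimension the optimal clusters are
#' contiguous in sorted order, so the optimum is found by dynamic programming
#' over the n-1 sorted split points using prefix sums — deterministic, with no
#' random initialization. Equal-cost splits are resolved toward the smaller
#' high (sensitive) cluster; a constant vector yields the degenerate split
#' with all points in the low cluster and score 0.
#'
#' @param v numeric vector, length >= 2.
#' @return list with `assignment` (factor `"resistant"`/`"sensitive"` aligned
#'   to `v`; sensitive = higher-centroid cluster), `centroids` = c(low, high),
#'   `score` = high - low (>= 0), and `wcss`, the optimal within-cluster sum
#'   of squares.
#' @export
two_means_1d <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 2L, all(is.finite(v)))
  n <- length(v)
  v <- unname(v)
  ord <- order(v)
  w <- v[ord]
  if (w[1L] == w[n]) {
    return(list(
      assignment = factor(rep("resistant", n), levels = c("resistant", "sensitive")),
      centroids = c(low = w[1L], high = w[1L]), score = 0, wcss = 0))
  }
  cs <- cumsum(w)
  css <- cumsum(w * w)
  s <- seq_len(n - 1L)                      # size of the low cluster
  m1 <- cs[s] / s
  m2 <- (cs[n] - cs[s]) / (n - s)
  wcss <- (css[s] - cs[s]^2 / s) + ((css[n] - css[s]) - (cs[n] - cs[s])^2 / (n - s))
  best <- max(which(wcss <= min(wcss)))     # tie -> smaller sensitive cluster
  lab <- rep("resistant", n)
  lab[ord[(best + 1L):n]] <- "sensitive"
  list(assignment = factor(lab, levels = c("resistant", "sensitive")),
       centroids = c(low = m1[best], high = m2[best]),
       score = m2[best] - m1[best],
       wcss = wcss[best])
}

#' Bimodality score of a gene-set profile
#'
#' The gap between the two centroids of the exact 2-means clustering of the
#' column-mean profile. For binary input the score lies in [0, 1]; it reaches
#' 1 only when every line is all-hit or all-miss with both kinds present, and
#' is 0 for a constant profile (including all-toxic and all-resistant sets) —
#' the score deliberately favours bimodal over universally toxic sets.
#'
#' @param P numeric r x n profile matrix.
#' @return scalar score >= 0.
#' @export
bimodality_score <- function(P) {
  two_means_1d(column_mean_profile(P))$score
}

# Vectorized scorer: one score per row of the B x n matrix V of profiles.
# Same split rule as two_means_1d; used by the permutation null machinery.
two_means_scores <- function(V) {
  B <- nrow(V); n <- ncol(V)
  W <- matrix(V[order(row(V), V)], B, n, byrow = TRUE)  # row-wise sort
  U <- 1 * outer(seq_len(n), seq_len(n), `<=`)          # prefix-sum operator
  cs <- W %*% U
  css <- (W * W) %*% U
  s <- seq_len(n - 1L)
  Sm <- matrix(s, B, n - 1L, byrow = TRUE)
  lowss <- css[, s, drop = FALSE] - cs[, s, drop = FALSE]^2 / Sm
  highss <- (css[, n] - css[, s, drop = FALSE]) -
    (cs[, n] - cs[, s, drop = FALSE])^2 / (n - Sm)
  wcss <- lowss + highss
  best <- max.col(-wcss, ties.method = "last")
  idx <- cbind(seq_len(B), best)
  m1 <- cs[idx] / best
  m2 <- (cs[, n] - cs[idx]) / (n - best)
  sc <- m2 - m1
  sc[W[, 1L] == W[, n]] <- 0                # constant profiles
  sc
}
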