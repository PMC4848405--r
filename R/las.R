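#' Standardize a matrix for LAS biclustering
#'
#' Subtracts the global mean and divides by the global standard deviation.
#' The LAS significance score models the matrix entries as standard Gaussian
#' noise, which is meaningless on a raw \{0,1\} hit matrix; standardizing a
#' binary matrix maps ones to (1-p)/sigma and zeros to -p/sigma where p is
#' the overall hit rate.
#'
#' @param M a [screen_matrix()] or a numeric matrix.
#' @return a numeric matrix with global mean 0 and sd 1.
#' @export
standardize_matrix <- function(M) {
  v <- if (inherits(M, "screen_matrix")) M$values else M
  stopifnot(is.matrix(v), !anyNA(v))
  s <- stats::sd(v)
  if (s == 0) stop("matrix has zero variance; cannot standardize")
  out <- (v - mean(v)) / s
  dimnames(out) <- dimnames(v)
  out
}

#' LAS significance score of a submatrix
#'
#' S(k, l, avg) = -log[ C(m,k) C(n,l) Phi(-avg sqrt(kl)) ]: the negative log
#' of a Bonferroni-style bound on the probability that any k x l submatrix of
#' an m x n standard Gaussian matrix attains average `avg`. Computed with
#' log-gamma binomial coefficients and the log-scale normal tail
#' (`pnorm(log.p = TRUE)`, whose asymptotic expansion keeps the score finite
#' for arbitrarily large `avg * sqrt(kl)`).
#'
#' @param k,l submatrix row/column counts.
#' @param avg submatrix average (on the standardized scale).
#' @param m,n matrix dimensions.
#' @return scalar (or vector, all arguments recycle) score; larger = more
#'   surprising under the Gaussian null.
#' @export
las_score <- function(k, l, avg, m, n) {
  stopifnot(all(k >= 1), all(l >= 1), all(k <= m), all(l <= n))
  -(lchoose(m, k) + lchoose(n, l) +
      stats::pnorm(-avg * sqrt(k * l), log.p = TRUE))
}

# One alternating-maximization pass: given the current column set, choose the
# best row count k (rows = top-k row sums over those columns), then
# symmetrically for columns; repeat to a fixed point.
las_search_once <- function(X, cols) {
  m <- nrow(X); n <- ncol(X)
  rows <- NULL
  repeat {
    rs <- if (length(cols) == 1L) X[, cols] else rowSums(X[, cols, drop = FALSE])
    ord <- order(rs, decreasing = TRUE)
    csum <- cumsum(rs[ord])
    k_all <- seq_len(m)
    sc <- las_score(k_all, length(cols), csum / (k_all * length(cols)), m, n)
    k <- which.max(sc)
    new_rows <- sort(ord[seq_len(k)])
    cs <- if (length(new_rows) == 1L) X[new_rows, ] else colSums(X[new_rows, , drop = FALSE])
    ordc <- order(cs, decreasing = TRUE)
    csumc <- cumsum(cs[ordc])
    l_all <- seq_len(n)
    scc <- las_score(length(new_rows), l_all, csumc / (length(new_rows) * l_all), m, n)
    l <- which.max(scc)
    new_cols <- sort(ordc[seq_len(l)])
    if (identical(new_rows, rows) && identical(new_cols, cols))
      return(list(rows = rows, cols = cols, score = scc[l],
                  avg = csumc[l] / (length(new_rows) * l)))
    rows <- new_rows; cols <- new_cols
  }
}

#' Find the single best bicluster by randomized LAS search
#'
#' Runs the alternating row/column maximization from `restarts` random
#' initial column subsets and keeps the best-scoring fixed point. Each step
#' scans every candidate row count (or column count) using sorted partial
#' sums, so for a given side the step is exactly optimal. Deterministic under
#' `seed`.
#'
#' @param X standardized numeric matrix (see [standardize_matrix()]).
#' @param restarts random restarts (default 1000).
#' @param seed integer seed.
#' @return object of class `bicluster`: list with `rows`, `cols` (integer
#'   indices), `row_ids`, `col_ids` (labels, when `X` has dimnames), `k`, `l`,
#'   `avg` and `score`.
#' @export
find_bicluster <- function(X, restarts = 1000L, seed = NULL) {
  stopifnot(is.matrix(X), restarts >= 1L)
  n <- ncol(X)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      l0 <- sample.int(n, 1L)
      cols <- sort(sample.int(n, l0))
      cand <- las_search_once(X, cols)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    structure(list(rows = best$rows, cols = best$cols,
                   row_ids = rownames(X)[best$rows],
                   col_ids = colnames(X)[best$cols],
                   k = length(best$rows), l = length(best$cols),
                   avg = best$avg, score = best$score),
              class = "bicluster")
  })
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d x %d, avg %.3f, score %.2f\n",
              x$k, x$l, x$avg, x$score))
  invisible(x)
}

#' Iterative LAS bicluster extraction
#'
#' Repeatedly finds the best bicluster, converts its score to a
#' Bonferroni-corrected p-value (p = exp(-score), multiplied by the number of
#' extraction rounds attempted, capped at 1), accepts it while p < `alpha`,
#' and residualizes: the accepted bicluster's average is subtracted from its
#' own cells only, so the same block cannot dominate subsequent rounds.
#'
#' @param M a [screen_matrix()] or numeric matrix; standardized internally.
#' @param max_biclusters maximum number of extraction rounds.
#' @param alpha significance threshold on the corrected p (default 1e-5).
#' @param restarts random restarts per round.
#' @param seed integer seed.
#' @return list of accepted `bicluster` objects, each with `p_bonferroni`
#'   added; possibly empty.
#' @export
las_iterate <- function(M, max_biclusters = 50L, alpha = 1e-5,
                        restarts = 1000L, seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1, max_biclusters >= 1L)
  X <- if (inherits(M, "screen_matrix")) standardize_matrix(M) else M
  out <- list()
  for (round in seq_len(max_biclusters)) {
    bc <- find_bicluster(X, restarts = restarts, seed = derive_seed(seed, round))
    p <- min(exp(-bc$score), 1) * round
    if (p >= alpha) break
    bc$p_bonferroni <- min(p, 1)
    out[[length(out) + 1L]] <- bc
    X[bc$rows, bc$cols] <- X[bc$rows, bc$cols] - bc$avg
  }
  out
}

#' Hypergeometric gene-set enrichment of a bicluster
#'
#' For each gene set, the upper-tail hypergeometric probability of at least
#' the observed overlap between the set and the bicluster's genes, drawn from
#' a universe of `universe` genes (the genes in the screen matrix), with
#' Benjamini-Hochberg adjustment and flagging at `fdr`.
#'
#' @param bicluster_rows character vector of bicluster gene ids.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of all screened gene ids.
#' @param fdr BH significance level (default 0.05).
#' @return data.frame with `set_name, set_size, overlap, p, p_adj,
#'   significant`, sorted by p; sets with no member in the universe are
#'   dropped and reported in attribute `skipped`.
#' @export
enrich_sets <- function(bicluster_rows, collection, universe, fdr = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  bic <- intersect(unique(bicluster_rows), universe)
  N <- length(universe); nb <- length(bic)
  nm <- names(collection$sets)
  rows <- list(); skipped <- character(0)
  for (i in seq_along(nm)) {
    memb <- intersect(unique(collection$sets[[i]]), universe)
    K <- length(memb)
    if (K == 0L) { skipped <- c(skipped, nm[i]); next }
    x <- length(intersect(memb, bic))
    p <- exp(log_tail_p(x, K, N, nb))
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = nm[i], set_size = K, overlap = x, p = p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set maps to the universe")
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= fdr
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
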