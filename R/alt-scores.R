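# log P(X >= x) for X ~ Hypergeometric(N total, K successes, n draws).
# phyper's log-scale upper tail is numerically stable far into the tail.
# Vectorizes over all arguments.
log_tail_p <- function(x, K, N, n) {
  ifelse(x <= 0, 0,
         stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Upper-tail hypergeometric probability of per-line hit enrichment
#'
#' P(X >= hits_in_set) for X ~ Hypergeometric(N = genes_total,
#' K = hits_in_line, n = set_size): the probability that drawing the set's
#' genes at random from the screened genome would capture at least the
#' observed number of that line's hits.
#'
#' @param hits_in_set observed hits of the line within the set.
#' @param set_size number of (mapped) genes in the set.
#' @param hits_in_line total hits of the line across the screen.
#' @param genes_total number of screened genes.
#' @return probability in (0, 1].
#' @export
line_tail_p <- function(hits_in_set, set_size, hits_in_line, genes_total) {
  if (hits_in_set < 0 || set_size > genes_total || hits_in_line > genes_total ||
      hits_in_set > min(set_size, hits_in_line))
    stop("inconsistent hypergeometric counts")
  exp(log_tail_p(hits_in_set, hits_in_line, genes_total, set_size))
}

# Sum over lines of log upper-tail probabilities for a binary profile P,
# given the full matrix's column hit totals and gene count.
hypergeom_log_score <- function(P, col_hits, genes_total) {
  r <- nrow(P)
  sum(log_tail_p(colSums(P), col_hits, genes_total, r))
}

#' Per-line hypergeometric product score of a gene set
#'
#' For each cell line, the upper-tail hypergeometric probability of the
#' number of hit knockdowns within the set; the per-line probabilities are
#' multiplied across lines (summed in log space, which avoids underflow on
#' panels of a dozen or more lines). Smaller log scores are more extreme.
#' Unlike the bimodality score, this statistic rewards universal toxicity as
#' much as subgroup-specific toxicity.
#'
#' @param M a binary-flavor [screen_matrix()].
#' @param set character vector of gene symbols.
#' @param B permutation replicates for the significance test (0 skips it).
#' @param seed integer seed.
#' @param min_mapped minimum mapped set size.
#' @return list of class `hypergeom_set_score` with `r`, `per_line_p`,
#'   `log_score` and `p_perm` (NA when `B = 0`); `NULL` when the set maps
#'   below `min_mapped`.
#' @export
set_score_hypergeom <- function(M, set, B = 1000L, seed = NULL,
                                min_mapped = 3L) {
  stopifnot(inherits(M, "screen_matrix"))
  if (M$flavor != "binary") stop("set_score_hypergeom expects a binary matrix")
  ex <- extract_profile(M, set, min_mapped = min_mapped)
  if (ex$skipped) return(NULL)
  col_hits <- colSums(M$values)
  logp <- log_tail_p(colSums(ex$profile), col_hits, nrow(M$values), ex$r)
  names(logp) <- M$line_ids
  p_perm <- NA_real_
  if (B > 0) {
    pr <- perm_pvalue_profile(M, ex$profile, B = B, seed = seed,
                              statistic = "hypergeom")
    p_perm <- pr$p
  }
  structure(list(set_name = NULL, r = ex$r, per_line_p = exp(logp),
                 log_score = sum(logp), p_perm = p_perm),
            class = "hypergeom_set_score")
}

#' Rank gene sets by the hypergeometric product score
#'
#' The alternative to [rank_complexes()]: every mapped set is scored by
#' [set_score_hypergeom()], permutation p-values use the same global null as
#' the bimodality test (with the log score as statistic, one-sided toward
#' small values), and Storey q-values control the FDR. In practice this
#' statistic flags far more sets than the bimodality score because it cannot
#' distinguish bimodal from universally toxic sets.
#'
#' @inheritParams rank_complexes
#' @return data.frame, one row per mapped set, sorted by ascending log score:
#'   `set_name, r_mapped, log_score, p_perm, q, significant`.
#' @export
rank_complexes_hypergeom <- function(M, collection, B = 1000L, seed = NULL,
                                     fdr = 0.10, min_mapped = 3L) {
  stopifnot(inherits(M, "screen_matrix"),
            inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("empty gene-set collection")
  nm <- names(collection$sets)
  rows <- list()
  for (i in seq_along(nm)) {
    sc <- set_score_hypergeom(M, collection$sets[[i]], B = B,
                              seed = derive_seed(seed, i),
                              min_mapped = min_mapped)
    if (is.null(sc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = nm[i], r_mapped = sc$r, log_score = sc$log_score,
      p_perm = sc$p_perm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set mapped to at least min_mapped rows")
  res$q <- storey_qvalues(res$p_perm)
  res$significant <- res$q <= fdr
  res <- res[order(res$log_score, res$set_name), ]
  rownames(res) <- NULL
  res
}

#' z-test set score (negative control)
#'
#' Compares the mean of a set's (continuous) values against the background
#' distribution with a one-sample z-test. Documented negative control only:
#' screen viability scores are far from normal, and even on normal data this
#' statistic prioritizes universally toxic over bimodal sets. Not a supported
#' scoring mode.
#'
#' @param M a continuous- or z-flavor [screen_matrix()].
#' @param set gene symbols.
#' @param min_mapped minimum mapped size.
#' @return list with `mean_set`, `z` and `p` (lower tail: more essential),
#'   or `NULL` if unmapped.
#' @keywords internal
set_score_ztest <- function(M, set, min_mapped = 3L) {
  ex <- extract_profile(M, set, min_mapped = min_mapped)
  if (ex$skipped) return(NULL)
  x <- as.vector(M$values)
  mu <- mean(x); sdev <- stats::sd(x)
  mean_set <- mean(ex$profile)
  z <- (mean_set - mu) / (sdev / sqrt(length(ex$profile)))
  list(mean_set = mean_set, z = z, p = stats::pnorm(z))
}
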