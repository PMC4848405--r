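#' Fisher's exact test on a clustered gene-set profile
#'
#' Tabulates the entries of a binary profile into a 2x2 contingency table —
#' rows: non-viable (entry 1) vs viable (entry 0) knockdowns; columns: lines
#' in the sensitive vs the resistant cluster — and applies a two-sided
#' Fisher's exact test. If either cluster is empty the test is undefined and
#' p = 1 is returned with `degenerate = TRUE`.
#'
#' @param P binary r x n profile matrix.
#' @param assignment factor of length n with levels `resistant`/`sensitive`
#'   (as produced by [two_means_1d()]).
#' @return list with `p`, the 2x2 `table`, and `degenerate`.
#' @export
fisher_test_profile <- function(P, assignment) {
  stopifnot(is.matrix(P), length(assignment) == ncol(P))
  sens <- assignment == "sensitive"
  if (!any(sens) || all(sens))
    return(list(p = 1,
                table = matrix(0L, 2L, 2L,
                               dimnames = list(c("nonviable", "viable"),
                                               c("sensitive", "resistant"))),
                degenerate = TRUE))
  tab <- matrix(c(sum(P[, sens]), sum(P[, sens] == 0),
                  sum(P[, !sens]), sum(P[, !sens] == 0)),
                2L, 2L,
                dimnames = list(c("nonviable", "viable"),
                                c("sensitive", "resistant")))
  list(p = stats::fisher.test(tab)$p.value, table = tab, degenerate = FALSE)
}

#' Score and rank gene sets for bimodal cell-line sensitivity
#'
#' For every gene set that maps to at least `min_mapped` rows of the screen,
#' computes the column-mean profile, the exact 2-means clustering, the
#' bimodality score (centroid gap), a global-permutation p-value, Storey
#' q-values across sets, and (for binary input) a two-sided Fisher's exact
#' test with Bonferroni adjustment over the sets tested. Continuous
#' (Achilles-style) matrices are scored on the same machinery without
#' binarization; the Fisher columns are then NA.
#'
#' @param M a binary- or continuous-flavor [screen_matrix()].
#' @param collection a [gene_set_collection()].
#' @param B permutation replicates per set (default 1000).
#' @param seed integer seed governing all permutation draws.
#' @param fdr significance level on the q-value (default 0.10).
#' @param min_mapped minimum mapped set size (default 3).
#' @return a data.frame, one row per mapped set, sorted by descending score:
#'   `set_name, r_mapped, score, c_low, c_high, p_perm, q, p_fisher,
#'   p_fisher_adj, significant, sensitive_lines, resistant_lines`. Skipped
#'   sets and unmapped symbols are reported in attributes `skipped` and
#'   `unmapped`.
#' @export
rank_complexes <- function(M, collection, B = 1000L, seed = NULL,
                           fdr = 0.10, min_mapped = 3L) {
  stopifnot(inherits(M, "screen_matrix"),
            inherits(collection, "gene_set_collection"))
  if (!M$flavor %in% c("binary", "continuous"))
    stop("rank_complexes expects a binary or continuous matrix")
  if (length(collection$sets) == 0L) stop("empty gene-set collection")
  nm <- names(collection$sets)
  rows <- vector("list", length(nm))
  skipped <- character(0)
  unmapped <- list()
  for (i in seq_along(nm)) {
    ex <- extract_profile(M, collection$sets[[i]], min_mapped = min_mapped)
    if (length(ex$unmapped)) unmapped[[nm[i]]] <- ex$unmapped
    if (ex$skipped) {
      skipped <- c(skipped, nm[i])
      next
    }
    P <- ex$profile
    km <- two_means_1d(column_mean_profile(P))
    pr <- perm_pvalue_profile(M, P, B = B, seed = derive_seed(seed, i),
                              statistic = "bimodality")
    fis <- if (M$flavor == "binary") fisher_test_profile(P, km$assignment)
           else list(p = NA_real_)
    sens <- km$assignment == "sensitive"
    rows[[i]] <- data.frame(
      set_name = nm[i], r_mapped = ex$r, score = km$score,
      c_low = unname(km$centroids["low"]), c_high = unname(km$centroids["high"]),
      p_perm = pr$p, p_fisher = fis$p,
      sensitive_lines = paste(M$line_ids[sens], collapse = ","),
      resistant_lines = paste(M$line_ids[!sens], collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set mapped to at least min_mapped rows")
  res$q <- storey_qvalues(res$p_perm)
  res$p_fisher_adj <- pmin(res$p_fisher * nrow(res), 1)
  res$significant <- res$q <= fdr
  res <- res[order(-res$score, res$p_perm, res$set_name), ]
  res <- res[, c("set_name", "r_mapped", "score", "c_low", "c_high",
                 "p_perm", "q", "p_fisher", "p_fisher_adj", "significant",
                 "sensitive_lines", "resistant_lines")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "unmapped") <- unmapped
  res
}

#' Write a ranking table to TSV
#'
#' @param x a data.frame as returned by [rank_complexes()] or
#'   [rank_complexes_hypergeom()].
#' @param path output path.
#' @param header_comments optional character vector written as `# `-prefixed
#'   header lines (e.g. the run seed).
#' @export
write_ranking_tsv <- function(x, path, header_comments = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con, sep = "\n")
  writeLines(paste(colnames(x), collapse = "\t"), con, sep = "\n")
  body <- apply(x, 1L, function(r) paste(as.character(r), collapse = "\t"))
  if (length(body)) writeLines(unname(body), con, sep = "\n")
  invisible(path)
}
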