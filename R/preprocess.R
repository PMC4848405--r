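#' Batch-wise robust Z scores
#'
#' For each experimental batch, z = (value - batch median) / batch MAD, where
#' the MAD is the bare median absolute deviation from the batch median (no
#' 1.4826 consistency constant). Robust Z scores are far less sensitive to the
#' strong outliers typical of viability screens than mean/sd Z scores.
#'
#' @param raw a raw-flavor [screen_matrix()] whose `batch` field (or the
#'   `batch` argument) labels every entry, either per row or per entry.
#' @param batch optional batch labels overriding `raw$batch`.
#' @return a z-flavor [screen_matrix()] of the same shape.
#' @export
robust_z <- function(raw, batch = NULL) {
  stopifnot(inherits(raw, "screen_matrix"))
  if (raw$flavor != "raw") stop("robust_z expects a raw-flavor matrix")
  batch <- batch %||% raw$batch
  if (is.null(batch)) stop("robust_z requires batch labels")
  v <- raw$values
  lab <- if (is.matrix(batch)) {
    if (!all(dim(batch) == dim(v))) stop("per-entry batch labels must match matrix dimensions")
    as.character(batch)
  } else {
    if (length(batch) != nrow(v)) stop("per-row batch labels must have one label per gene row")
    rep(as.character(batch), times = ncol(v))
  }
  if (anyNA(lab)) stop("unknown (missing) batch label")
  z <- v
  for (b in unique(lab)) {
    idx <- which(lab == b)
    x <- v[idx]
    fin <- x[is.finite(x)]
    if (length(fin) < 3L)
      stop("batch '", b, "' has fewer than 3 finite entries")
    med <- stats::median(fin)
    mad0 <- stats::median(abs(fin - med))
    if (mad0 == 0)
      stop("degenerate batch '", b, "': MAD is zero")
    z[idx] <- (x - med) / mad0
  }
  screen_matrix(z, flavor = "z", gene_ids = raw$gene_ids,
                line_ids = raw$line_ids)
}

#' Combine two libraries' Z matrices by entrywise minimum
#'
#' Scores screened with two independent siRNA libraries are merged by taking
#' the minimum Z per gene/line: disagreement is treated as a false negative in
#' one library, so a hit in either library is kept. Alignment is by gene
#' symbol and line id, not by position; genes present in only one input are
#' retained with their single value.
#'
#' @param za,zb z-flavor [screen_matrix()] objects.
#' @return a z-flavor [screen_matrix()] over the union of genes and the shared
#'   cell lines.
#' @export
combine_min <- function(za, zb) {
  stopifnot(inherits(za, "screen_matrix"), inherits(zb, "screen_matrix"))
  if (za$flavor != "z" || zb$flavor != "z")
    stop("combine_min expects z-flavor matrices")
  lines <- intersect(za$line_ids, zb$line_ids)
  if (length(lines) == 0L) stop("no shared cell lines between the two inputs")
  genes <- union(za$gene_ids, zb$gene_ids)
  if (anyDuplicated(za$gene_ids) || anyDuplicated(zb$gene_ids))
    stop("combine_min requires unique gene ids within each input")
  out <- matrix(NA_real_, length(genes), length(lines),
                dimnames = list(genes, lines))
  a <- za$values[, lines, drop = FALSE]; rownames(a) <- za$gene_ids
  b <- zb$values[, lines, drop = FALSE]; rownames(b) <- zb$gene_ids
  out[za$gene_ids, ] <- a
  only_b <- setdiff(zb$gene_ids, za$gene_ids)
  out[only_b, ] <- b[only_b, , drop = FALSE]
  shared <- intersect(za$gene_ids, zb$gene_ids)
  out[shared, ] <- pmin(a[shared, , drop = FALSE], b[shared, , drop = FALSE])
  screen_matrix(out, flavor = "z", gene_ids = genes, line_ids = lines)
}

#' Binarize Z scores into hit calls
#'
#' Entries strictly below the threshold become 1 (hit: the knockdown kills or
#' arrests the line); everything else becomes 0.
#'
#' @param z a z-flavor [screen_matrix()] with no NA.
#' @param threshold hit threshold on the robust Z scale; default -3.0.
#' @return a binary-flavor [screen_matrix()].
#' @export
binarize <- function(z, threshold = -3.0) {
  stopifnot(inherits(z, "screen_matrix"))
  if (z$flavor != "z") stop("binarize expects a z-flavor matrix")
  if (anyNA(z$values)) stop("binarize expects no NA entries")
  screen_matrix((z$values < threshold) * 1, flavor = "binary",
                gene_ids = z$gene_ids, line_ids = z$line_ids)
}

#' Impute missing values with row medians
#'
#' Replaces NaN/NA entries of a continuous essentiality matrix by the median
#' of the finite entries of their row. Finite entries are unchanged.
#'
#' @param x a continuous-flavor [screen_matrix()].
#' @return the imputed [screen_matrix()].
#' @export
impute_row_median <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  if (x$flavor != "continuous") stop("impute_row_median expects a continuous-flavor matrix")
  v <- x$values
  bad <- !is.finite(v)
  if (!any(bad)) return(x)
  all_bad <- rowSums(!bad) == 0L
  if (any(all_bad))
    stop("row(s) with no finite values: ",
         paste(utils::head(x$gene_ids[all_bad], 5L), collapse = ", "))
  meds <- apply(v, 1L, function(r) stats::median(r[is.finite(r)]))
  v[bad] <- meds[row(v)[bad]]
  out <- x
  out$values <- v
  out
}
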