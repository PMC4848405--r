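#' Screen matrix container
#'
#' A `screen_matrix` holds a gene x cell-line viability matrix together with
#' its flavor and optional per-row batch labels. Flavors:
#' \describe{
#'   \item{raw}{plate-normalized viability values, batch-labelled}
#'   \item{z}{batch-wise robust Z scores (dimensionless)}
#'   \item{binary}{hit indicators: 1 = knockdown kills/arrests the line}
#'   \item{continuous}{continuous essentiality values (Achilles convention:
#'     lower = more essential)}
#' }
#'
#' @param values numeric matrix, genes in rows, cell lines in columns.
#' @param flavor one of `"raw"`, `"z"`, `"binary"`, `"continuous"`.
#' @param gene_ids,line_ids row/column labels; taken from `dimnames(values)`
#'   when omitted. Labels must be non-empty; line ids must be unique. Duplicate
#'   gene ids are retained (Achilles keeps multiple rows per symbol) and
#'   disambiguated internally with a `#k` suffix stored in `gene_keys`.
#' @param batch optional per-row batch labels (length `nrow`), or a matrix of
#'   per-entry labels with the same dimensions as `values`.
#' @return an object of class `screen_matrix` with fields `values`, `flavor`,
#'   `batch`, `gene_ids` (original symbols, possibly duplicated) and
#'   `gene_keys` (unique internal row keys).
#' @export
screen_matrix <- function(values, flavor = c("raw", "z", "binary", "continuous"),
                          gene_ids = NULL, line_ids = NULL, batch = NULL) {
  flavor <- match.arg(flavor)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  storage.mode(values) <- "double"
  gene_ids <- gene_ids %||% rownames(values)
  line_ids <- line_ids %||% colnames(values)
  if (is.null(gene_ids) || is.null(line_ids))
    stop("gene and line identifiers are required (dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  line_ids <- as.character(line_ids)
  if (length(gene_ids) != nrow(values) || length(line_ids) != ncol(values))
    stop("label lengths do not match matrix dimensions")
  if (any(!nzchar(gene_ids)) || any(!nzchar(line_ids)))
    stop("empty gene or line identifiers are not allowed")
  if (anyDuplicated(line_ids)) stop("cell-line identifiers must be unique")
  gene_keys <- make_gene_keys(gene_ids)
  if (flavor == "binary") {
    v <- values[!is.na(values)]
    if (!all(v %in% c(0, 1))) stop("binary flavor requires entries in {0,1}")
    if (anyNA(values)) stop("binary flavor admits no NA entries")
  }
  if (flavor == "z" && anyNA(values))
    stop("z flavor admits no NA entries")
  if (!is.null(batch)) {
    if (is.matrix(batch)) {
      if (!all(dim(batch) == dim(values)))
        stop("per-entry batch labels must match matrix dimensions")
    } else if (length(batch) != nrow(values)) {
      stop("per-row batch labels must have one label per gene row")
    }
  }
  dimnames(values) <- list(gene_keys, line_ids)
  structure(list(values = values, flavor = flavor, batch = batch,
                 gene_ids = gene_ids, gene_keys = gene_keys,
                 line_ids = line_ids),
            class = "screen_matrix")
}

# Achilles convention: duplicated symbols kept, internal keys disambiguated.
make_gene_keys <- function(gene_ids) {
  if (!anyDuplicated(gene_ids)) return(gene_ids)
  keys <- gene_ids
  dup <- duplicated(gene_ids) | duplicated(gene_ids, fromLast = TRUE)
  idx <- stats::ave(seq_along(gene_ids), gene_ids, FUN = seq_along)
  keys[dup] <- paste0(gene_ids[dup], "#", idx[dup])
  keys
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix [%s]: %d genes x %d cell lines\n",
              x$flavor, nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch))
    cat(sprintf("  batches: %s\n",
                paste(unique(as.character(x$batch)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.screen_matrix <- function(x) dim(x$values)

#' Read a screen matrix from TSV
#'
#' Expects a header row of cell-line ids and a first column of gene ids.
#' The empty-string value `NA` in cells is read as `NA`.
#'
#' @param path file path.
#' @param flavor matrix flavor (see [screen_matrix()]).
#' @param batch optional per-row batch labels.
#' @return a [screen_matrix()].
#' @export
read_matrix_tsv <- function(path, flavor = "z", batch = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("matrix TSV needs a header and at least one row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  bad <- which(lengths(fields[-1L]) != ncol_expected)
  if (length(bad))
    stop(sprintf("ragged row in %s at line %d (expected %d fields, got %d)",
                 path, bad[1L] + 1L, ncol_expected, lengths(fields[-1L])[bad[1L]]))
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- vapply(body, function(f) {
    cells <- f[-1L]
    cells[cells %in% c("NA", "NaN")] <- NA
    as.numeric(cells)
  }, numeric(ncol_expected - 1L))
  values <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expected - 1L)
  dimnames(values) <- list(gene_ids, header[-1L])
  screen_matrix(values, flavor = flavor, gene_ids = gene_ids,
                line_ids = header[-1L], batch = batch)
}

#' Write a screen matrix to TSV
#'
#' Full float precision (values survive a write/read round trip bit-exactly),
#' UTF-8, LF line endings. The header's first field is `gene`.
#'
#' @param x a [screen_matrix()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "screen_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", x$line_ids), collapse = "\t"), con, sep = "\n")
  vals <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  vals[is.na(x$values)] <- "NA"
  body <- paste(x$gene_ids,
                apply(vals, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' One-pass plate median normalization
#'
#' Subtracts row medians then column medians, once each, in that order.
#' Intended for raw plate data whose upstream normalization is missing.
#'
#' @param x a raw-flavor [screen_matrix()].
#' @return the normalized `screen_matrix`.
#' @export
normalize_medians <- function(x) {
  stopifnot(inherits(x, "screen_matrix"))
  v <- x$values
  v <- sweep(v, 1L, apply(v, 1L, stats::median, na.rm = TRUE))
  v <- sweep(v, 2L, apply(v, 2L, stats::median, na.rm = TRUE))
  out <- x
  out$values <- v
  out
}
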