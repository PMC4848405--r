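#' Gene-set collection
#'
#' Named gene sets (typically protein complexes, e.g. from CORUM) mapped by
#' gene symbol. Members are deduplicated within each set; set names must be
#' unique and every set must have at least one member.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param source free-text provenance tag (e.g. `"CORUM"`).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.list(sets))
    stop("`sets` must be a named list")
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("`sets` must be a named list")
  if (length(sets) == 0L)
    return(structure(list(sets = stats::setNames(list(), character(0)),
                          source = source),
                     class = "gene_set_collection"))
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         names(sets)[duplicated(names(sets))][1L])
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("every set needs at least one member")
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @param source provenance tag stored on the collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                 short[1L], path))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in ", path, ": ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, source = source)
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional per-set description column; defaults to `"na"`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- descriptions %||% rep("na", length(nm))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1)), con, sep = "\n")
  invisible(path)
}

#' Extract the sensitivity profile of a gene set
#'
#' Pulls the rows of `M` whose gene symbol belongs to `set`, preserving the
#' original column order, to give the r x n profile submatrix of the set.
#' Matching is exact and case-sensitive. Rows whose (possibly duplicated)
#' symbol matches are all retained.
#'
#' @param M a [screen_matrix()].
#' @param set character vector of gene symbols (deduplicated internally).
#' @param min_mapped minimum number of mapped rows (>= 2) for the profile to
#'   be usable; below it `NULL` is returned and the caller should skip the set.
#' @return a list with `profile` (r x n numeric matrix or `NULL` if skipped),
#'   `r` (mapped row count), `unmapped` (symbols absent from the screen) and
#'   `skipped` (logical).
#' @export
extract_profile <- function(M, set, min_mapped = 3L) {
  stopifnot(inherits(M, "screen_matrix"), min_mapped >= 2L)
  set <- unique(as.character(set))
  keep <- M$gene_ids %in% set
  unmapped <- setdiff(set, M$gene_ids)
  r <- sum(keep)
  if (r < min_mapped)
    return(list(profile = NULL, r = r, unmapped = unmapped, skipped = TRUE))
  list(profile = M$values[keep, , drop = FALSE], r = r,
       unmapped = unmapped, skipped = FALSE)
}
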