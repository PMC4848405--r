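#' Synthetic screen configuration
#'
#' Describes a synthetic perturbation-viability screen with known ground
#' truth: iid Bernoulli background hits, optional planted bimodal gene sets
#' (elevated hit probability on a subset of "sensitive" lines), optional
#' planted biclusters (mean-shifted blocks for the continuous generator),
#' decoy gene sets, and batch structure. The defaults are a desk-scale
#' version of a genome-wide screen on a 13-line panel: 2000 genes, background
#' hit rate 0.02, 50 gene sets of 5-30 members of which 5 are planted bimodal
#' (hit probability 0.8 on 4 sensitive lines, 0.05 elsewhere).
#'
#' @param m,n genes and cell lines.
#' @param p0 background hit probability.
#' @param n_sets total number of gene sets (planted + decoys).
#' @param set_sizes inclusive range of set sizes.
#' @param n_planted number of planted bimodal sets.
#' @param p_sens,p_res hit probability of planted-set genes on sensitive /
#'   non-sensitive lines (requires p_res < p_sens).
#' @param n_sensitive_lines sensitive lines per planted set.
#' @param planted_blocks list of `list(k=, l=, shift=)` blocks for the
#'   continuous generator (values shifted by `-shift`; positive shift = more
#'   essential).
#' @param batches number of per-row screening batches.
#' @param nan_frac fraction of missing values (continuous generator).
#' @param duplicate_rows extra duplicated gene rows (continuous generator,
#'   Achilles convention).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(m = 2000L, n = 13L, p0 = 0.02,
                             n_sets = 50L, set_sizes = c(5L, 30L),
                             n_planted = 5L, p_sens = 0.8, p_res = 0.05,
                             n_sensitive_lines = 4L,
                             planted_blocks = list(),
                             batches = 4L, nan_frac = 0, duplicate_rows = 0L) {
  stopifnot(m >= 1, n >= 2, p0 >= 0, p0 <= 1,
            n_planted <= n_sets, n_sensitive_lines < n)
  if (n_planted > 0 && !(p_res < p_sens && p_sens <= 1 && p_res >= 0))
    stop("planted sets require 0 <= p_res < p_sens <= 1")
  structure(list(m = as.integer(m), n = as.integer(n), p0 = p0,
                 n_sets = as.integer(n_sets), set_sizes = as.integer(set_sizes),
                 n_planted = as.integer(n_planted), p_sens = p_sens,
                 p_res = p_res, n_sensitive_lines = as.integer(n_sensitive_lines),
                 planted_blocks = planted_blocks, batches = as.integer(batches),
                 nan_frac = nan_frac, duplicate_rows = as.integer(duplicate_rows)),
            class = "synthetic_config")
}

synth_gene_ids <- function(m) sprintf("g%05d", seq_len(m))
synth_line_ids <- function(n) sprintf("L%02d", seq_len(n))

#' Generate a synthetic binary hit matrix with planted gene sets
#'
#' Background entries are iid Bernoulli(p0). Each planted set occupies a
#' disjoint block of gene rows whose entries are Bernoulli(p_sens) on that
#' set's sensitive lines and Bernoulli(p_res) elsewhere. Decoy sets are
#' sampled from the remaining background rows. The returned manifest records
#' exactly how each planted object was constructed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed gives a bit-identical screen.
#' @return list with `matrix` (binary [screen_matrix()] with per-row batch
#'   labels), `collection` (a [gene_set_collection()] of planted + decoy
#'   sets) and `manifest` (list with one record per planted set).
#' @export
generate_binary <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  c0 <- config
  with_seed(seed, {
    genes <- synth_gene_ids(c0$m)
    lines <- synth_line_ids(c0$n)
    vals <- matrix(stats::rbinom(c0$m * c0$n, 1L, c0$p0), c0$m, c0$n,
                   dimnames = list(genes, lines))
    sizes <- sample(seq(c0$set_sizes[1], c0$set_sizes[2]), c0$n_sets,
                    replace = TRUE)
    planted_rows_needed <- sum(sizes[seq_len(c0$n_planted)])
    if (planted_rows_needed > c0$m)
      stop("planted rows exceed the number of genes")
    manifest <- list()
    sets <- list()
    next_row <- 1L
    for (i in seq_len(c0$n_planted)) {
      r <- sizes[i]
      rows <- next_row:(next_row + r - 1L)
      next_row <- next_row + r
      sens <- sort(sample.int(c0$n, c0$n_sensitive_lines))
      vals[rows, sens] <- stats::rbinom(r * length(sens), 1L, c0$p_sens)
      vals[rows, -sens] <- stats::rbinom(r * (c0$n - length(sens)), 1L, c0$p_res)
      nm <- sprintf("planted_%02d", i)
      sets[[nm]] <- genes[rows]
      manifest[[nm]] <- list(genes = genes[rows], sensitive_lines = lines[sens],
                             p_sens = c0$p_sens, p_res = c0$p_res)
    }
    background_rows <- if (next_row <= c0$m) next_row:c0$m else integer(0)
    for (i in seq_len(c0$n_sets - c0$n_planted)) {
      r <- sizes[c0$n_planted + i]
      sets[[sprintf("decoy_%03d", i)]] <-
        genes[sample(background_rows, min(r, length(background_rows)))]
    }
    batch <- rep_len(sprintf("batch%d", seq_len(c0$batches)), c0$m)
    list(matrix = screen_matrix(vals, flavor = "binary", batch = batch),
         collection = gene_set_collection(sets, source = "synthetic"),
         manifest = manifest)
  })
}

#' Generate a synthetic continuous essentiality matrix
#'
#' Achilles-style: iid standard Gaussian background with planted mean-shifted
#' blocks (`value - shift` inside each block; positive shift = lower values =
#' more essential), optional missing values, and optional duplicated gene
#' rows (kept as separate rows with the same symbol).
#'
#' @param config a [synthetic_config()]; uses `planted_blocks`, `nan_frac`
#'   and `duplicate_rows`.
#' @param seed integer seed.
#' @return list with `matrix` (continuous [screen_matrix()]) and `manifest`
#'   (one record per planted block).
#' @export
generate_continuous <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  c0 <- config
  with_seed(seed, {
    genes <- synth_gene_ids(c0$m)
    lines <- synth_line_ids(c0$n)
    vals <- matrix(stats::rnorm(c0$m * c0$n), c0$m, c0$n,
                   dimnames = list(genes, lines))
    manifest <- list()
    next_row <- 1L
    for (i in seq_along(c0$planted_blocks)) {
      b <- c0$planted_blocks[[i]]
      if (next_row + b$k - 1L > c0$m) stop("planted rows exceed the number of genes")
      rows <- next_row:(next_row + b$k - 1L)
      next_row <- next_row + b$k
      cols <- sort(sample.int(c0$n, b$l))
      vals[rows, cols] <- vals[rows, cols] - b$shift
      manifest[[sprintf("block_%02d", i)]] <-
        list(genes = genes[rows], lines = lines[cols], shift = b$shift)
    }
    if (c0$nan_frac > 0) {
      holes <- which(stats::runif(length(vals)) < c0$nan_frac)
      vals[holes] <- NA_real_
    }
    gene_ids <- genes
    if (c0$duplicate_rows > 0) {
      dup <- sample.int(c0$m, c0$duplicate_rows, replace = TRUE)
      vals <- rbind(vals, vals[dup, , drop = FALSE] +
                      stats::rnorm(c0$duplicate_rows * c0$n, sd = 0.1))
      gene_ids <- c(genes, genes[dup])
    }
    list(matrix = screen_matrix(vals, flavor = "continuous",
                                gene_ids = gene_ids, line_ids = lines),
         manifest = manifest)
  })
}

#' Size-bias experiment for the permutation test
#'
#' Generates a fully null binary screen and scores decoy sets spanning a
#' range of sizes, returning each set's size with its permutation p-value.
#' Used to check that the permutation significance test is not biased toward
#' larger or smaller gene sets: under the null, size and p-value should be
#' uncorrelated and p-values uniform within each size stratum.
#'
#' @param seed integer seed.
#' @param n_sets number of decoy sets (sizes cycled over `sizes`).
#' @param sizes inclusive size range, default 3-100.
#' @param m,n,p0 null screen dimensions and hit rate.
#' @param B permutation replicates per set.
#' @return data.frame with columns `size` and `p`.
#' @export
size_bias_experiment <- function(seed = NULL, n_sets = 1000L,
                                 sizes = c(3L, 100L), m = 2000L, n = 13L,
                                 p0 = 0.02, B = 1000L) {
  cfg <- synthetic_config(m = m, n = n, p0 = p0, n_sets = 0L, n_planted = 0L)
  sim <- generate_binary(cfg, seed = seed)
  M <- sim$matrix
  with_seed(derive_seed(seed, 1L), {
    size_vec <- rep_len(seq(sizes[1], sizes[2]), n_sets)
    p <- vapply(seq_len(n_sets), function(i) {
      set <- M$gene_ids[sample.int(m, size_vec[i])]
      permutation_pvalue(M, set, B = B, seed = derive_seed(seed, i + 1L))$p
    }, numeric(1))
    data.frame(size = size_vec, p = p)
  })
}
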