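#' Leave-one-out splits of a gene-set collection
#'
#' For every set whose mapped size is at least `min_size`, withholds one
#' uniformly random mapped member; the remaining members form the training
#' set. Reproducible under `seed`.
#'
#' @param M a [screen_matrix()] (defines which members map).
#' @param collection a [gene_set_collection()].
#' @param min_size minimum mapped set size to include (the usual choices are
#'   5 or 8).
#' @param seed integer seed.
#' @return named list, one element per eligible set: `list(withheld, training)`
#'   of gene symbols.
#' @export
loo_split <- function(M, collection, min_size = 5L, seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"), min_size >= 2L)
  with_seed(seed, {
    out <- list()
    for (nm in names(collection$sets)) {
      mapped <- intersect(unique(collection$sets[[nm]]), M$gene_ids)
      if (length(mapped) < min_size) next
      w <- mapped[sample.int(length(mapped), 1L)]
      out[[nm]] <- list(withheld = w, training = setdiff(mapped, w))
    }
    out
  })
}

#' Trapezoidal area under a ROC curve
#'
#' @param fpr,tpr coordinate vectors (need not be sorted; sorted internally).
#' @return scalar AUC in [0, 1].
#' @export
roc_auc <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr), length(fpr) >= 2L)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

# Empirical ROC points for scores/labels: thresholds swept over unique scores,
# predictions score >= t. Returns points from (0,0) to (1,1).
roc_points <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- sum(label == 1); neg <- sum(label == 0)
  if (pos == 0L || neg == 0L) return(NULL)
  o <- order(score, decreasing = TRUE)
  lab <- label[o]; sc <- score[o]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last index of each tie group
  data.frame(fpr = c(0, fp[keep] / neg), tpr = c(0, tp[keep] / pos))
}

# Stepwise-constant interpolation of a ROC curve onto an FPR grid:
# tpr(g) = max tpr among points with fpr <= g.
roc_interpolate <- function(curve, grid) {
  tpr_cummax <- cummax(curve$tpr)
  idx <- findInterval(grid, curve$fpr)
  out <- ifelse(idx >= 1L, tpr_cummax[pmax(idx, 1L)], 0)
  out[length(out)] <- 1
  out
}

#' Leave-one-out ROC benchmark of the 2-means clustering
#'
#' Per iteration: each eligible set is split leave-one-out; the 2-means
#' clustering and (optionally) the permutation significance test run on the
#' training members only. For each set whose training profile is significant
#' (q <= `gate_fdr`), every cell line contributes one test instance whose
#' predictor is the training column mean for that line and whose true label
#' is the withheld gene's hit indicator in that line — so the clustering's
#' sensitive/resistant partition is judged by whether it predicts the held-out
#' member's hit pattern. Instances are pooled into one ROC per iteration;
#' iteration curves are vertically averaged on a fixed FPR grid.
#'
#' @param M a binary-flavor [screen_matrix()].
#' @param collection a [gene_set_collection()].
#' @param min_size minimum mapped set size (5 or 8 typically).
#' @param n_iter number of leave-one-out iterations.
#' @param B permutation replicates for the training-set significance gate.
#' @param seed integer seed.
#' @param gate_fdr q-value threshold gating sets into the test pool
#'   (default 0.10). `NULL` disables the gate so every eligible set
#'   contributes instances — required to study the benchmark's calibration on
#'   data where nothing is significant.
#' @param grid_size number of evenly spaced FPR grid points (default 101).
#' @return object of class `roc_curve`: list with `fpr_grid`, `tpr_mean`,
#'   `auc` (area under the averaged curve), `auc_mean` (mean of per-iteration
#'   AUCs), `auc_per_iteration`, `n_iterations` (iterations that produced a
#'   curve) and `n_instances_per_iteration`.
#' @export
loo_roc <- function(M, collection, min_size = 5L, n_iter = 5L, B = 1000L,
                    seed = NULL, gate_fdr = 0.10, grid_size = 101L) {
  stopifnot(inherits(M, "screen_matrix"), n_iter >= 1L)
  if (M$flavor != "binary") stop("loo_roc expects a binary matrix")
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- list(); aucs <- numeric(0); n_inst <- integer(0)
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it)
    splits <- loo_split(M, collection, min_size = min_size, seed = it_seed)
    if (length(splits) == 0L) {
      warning("iteration ", it, ": no set reaches min_size; skipped")
      next
    }
    score <- numeric(0); label <- numeric(0)
    pvals <- numeric(length(splits)); profiles <- vector("list", length(splits))
    for (k in seq_along(splits)) {
      tr <- splits[[k]]$training
      ex <- extract_profile(M, tr, min_mapped = 2L)
      profiles[[k]] <- ex$profile
      pvals[k] <- if (is.null(gate_fdr)) 0 else
        perm_pvalue_profile(M, ex$profile, B = B,
                            seed = derive_seed(it_seed, k))$p
    }
    keep <- if (is.null(gate_fdr)) rep(TRUE, length(splits)) else
      storey_qvalues(pvals) <= gate_fdr
    if (!any(keep)) {
      warning("iteration ", it, ": no significant training set; skipped")
      next
    }
    for (k in which(keep)) {
      v <- column_mean_profile(profiles[[k]])
      w <- splits[[k]]$withheld
      y <- M$values[match(w, M$gene_ids), ]
      score <- c(score, v); label <- c(label, y)
    }
    pts <- roc_points(score, label)
    if (is.null(pts)) {
      warning("iteration ", it, ": single-class test labels; skipped")
      next
    }
    tprs[[length(tprs) + 1L]] <- roc_interpolate(pts, grid)
    aucs <- c(aucs, roc_auc(pts$fpr, pts$tpr))
    n_inst <- c(n_inst, length(label))
  }
  if (length(tprs) == 0L) stop("no iteration produced a ROC curve")
  tpr_mean <- Reduce(`+`, tprs) / length(tprs)
  structure(list(fpr_grid = grid, tpr_mean = tpr_mean,
                 auc = roc_auc(grid, tpr_mean),
                 auc_mean = mean(aucs), auc_per_iteration = aucs,
                 n_iterations = length(tprs),
                 n_instances_per_iteration = n_inst),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d iteration(s), mean AUC %.3f (averaged-curve AUC %.3f)\n",
              x$n_iterations, x$auc_mean, x$auc))
  invisible(x)
}
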