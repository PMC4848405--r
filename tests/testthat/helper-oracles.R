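# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: the clustering oracle enumerates every
# bipartition (not just sorted-contiguous splits), and the probability
# oracles sum log-factorial terms directly instead of calling phyper /
# fisher.test.

# All 2-subsets-of-{1..n} bipartitions, as a logical matrix with one
# assignment per row (element 1 always in cluster A; both clusters nonempty).
all_bipartitions <- function(n) {
  stopifnot(n >= 2L, n <= 16L)
  idx <- 0:(2^(n - 1L) - 1L)
  A <- matrix(FALSE, length(idx), n)
  A[, 1L] <- TRUE
  for (j in 2:n) A[, j] <- bitwAnd(idx, 2^(j - 2L)) > 0L
  A[-nrow(A), , drop = FALSE]                 # drop the all-in-A row
}

# Exhaustive optimal 2-clustering of v: minimal WCSS over all bipartitions,
# with the centroid gaps of every WCSS-optimal assignment.
oracle_two_means <- function(v, tol = 1e-12) {
  n <- length(v)
  A <- all_bipartitions(n)
  s1 <- as.vector(A %*% v); s2 <- as.vector(A %*% v^2)
  n1 <- rowSums(A); n2 <- n - n1
  tot1 <- sum(v); tot2 <- sum(v^2)
  wcss <- (s2 - s1^2 / n1) + ((tot2 - s2) - (tot1 - s1)^2 / n2)
  best <- min(wcss)
  opt <- wcss <= best + tol
  gaps <- abs(s1[opt] / n1[opt] - (tot1 - s1[opt]) / n2[opt])
  list(wcss = best, gaps = gaps)
}

# log n! from lgamma, for direct combinatorial evaluation.
lfact <- function(x) lgamma(x + 1)
lchoose_direct <- function(n, k) lfact(n) - lfact(k) - lfact(n - k)

# Upper-tail hypergeometric P(X >= x) by direct summation of choose ratios.
oracle_hyper_tail <- function(x, K, N, n) {
  if (x <= 0) return(1)
  supp <- max(0, n - (N - K)):min(n, K)
  supp <- supp[supp >= x]
  if (length(supp) == 0L) return(0)
  sum(exp(lchoose_direct(K, supp) + lchoose_direct(N - K, n - supp) -
            lchoose_direct(N, n)))
}

# Two-sided Fisher p for table (a b / c d): enumerate the support of the
# conditional distribution given margins, sum probabilities <= P(observed)
# (with the standard relative tolerance for ties).
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  supp <- max(0, c1 - (N - r1)):min(r1, c1)
  lp <- lchoose_direct(r1, supp) + lchoose_direct(N - r1, c1 - supp) -
    lchoose_direct(N, c1)
  pobs <- lp[supp == a]
  sum(exp(lp[lp <= pobs + log(1 + 1e-7)]))
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie), by all pairs.
oracle_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Small deterministic binary screen used by several tests.
tiny_screen <- function(m = 40L, n = 6L, seed = 101L) {
  gen <- generate_binary(synthetic_config(m = m, n = n, p0 = 0.1,
                                          n_sets = 4L, set_sizes = c(3L, 6L),
                                          n_planted = 1L, p_sens = 0.9,
                                          p_res = 0.05,
                                          n_sensitive_lines = 2L),
                         seed = seed)
  gen
}

# Fuzzed vectors for clustering property tests: mixes continuous values and
# coarse grids (ties) at lengths 2..10.
fuzz_vectors <- function(n_vectors, seed) {
  set.seed(seed)
  lapply(seq_len(n_vectors), function(i) {
    n <- sample(2:10, 1L)
    if (runif(1) < 0.5) round(runif(n, 0, 1) * 4) / 4 else runif(n)
  })
}
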