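---
title: "Scoring gene-set vulnerabilities in perturbation screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-set vulnerabilities in perturbation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnscreen)
```

## The problem

A genome-scale loss-of-function viability screen across a cell-line panel
produces, after hit calling, a binary matrix M (m genes × n lines) with
M_ij = 1 when knockdown of gene i kills or arrests line j. The scientific
question is not which single genes are essential, but which *functionally
coherent gene sets* — protein complexes, pathway modules — are essential to a
**subgroup** of the panel. Universally essential machinery is a poor drug
target (predicted toxicity extends to normal tissue); so is machinery nobody
depends on. The interesting signature is *bimodal*: a subset of lines is
strongly sensitive to loss of most members of the set, the rest are not.

## Preprocessing model

Raw plate-normalized viabilities are converted to robust Z scores within
experimental batches:

$$z = \frac{x - \mathrm{median}(x_{\text{batch}})}{\mathrm{MAD}(x_{\text{batch}})},$$

where MAD is the bare median absolute deviation from the batch median. No
1.4826 normal-consistency factor is applied: the threshold below is defined
on the same bare scale, and screens are far from Gaussian anyway — the pair
(bare MAD, threshold −3.0) is a self-consistent convention. A degenerate
batch (MAD = 0) or a batch with fewer than three finite values is an error,
not a silent pass-through.

Two siRNA libraries screening the same genes are merged by the entrywise
**minimum** of their Z matrices, aligned by gene symbol: disagreement between
libraries is attributed to false negatives, so a kill in either library is
believed. Genes screened by only one library are retained with their single
value — dropping them would silently shrink the screen. Hits are then called
by the strict cut z < −3.0 (exactly −3.0 is not a hit).

Continuous essentiality matrices (Achilles convention: lower value = more
essential) are supported without thresholding; missing entries are imputed
with row medians, and duplicated gene symbols are kept as separate rows with
internally disambiguated keys.

## The bimodality statistic

For a set mapping to r rows of M (profile P, r × n), the per-line mean-hit
vector $v_j = \frac{1}{r}\sum_i P_{ij}$ normalizes for set size. v is
partitioned by **exact 1-D 2-means**: because optimal univariate clusters
are contiguous in sorted order, the global optimum is found by scanning the
n − 1 sorted split points with prefix sums — O(n log n), deterministic, no
random initialization or restarts to tune. The score is the centroid gap
c_high − c_low ∈ [0, 1] for binary input; the higher-centroid cluster is the
*sensitive* subgroup (more hits = less viable).

Numerical conventions worth stating:

* a constant profile has no bimodality: score 0, all lines assigned
  resistant;
* ties between equal-cost splits resolve toward the **smaller** sensitive
  cluster (deterministic, and conservative about sensitivity calls);
* the score is invariant under row and column permutations of P, and equals
  1 exactly when every line is all-hit or all-miss with both kinds present.

The test suite checks the optimizer against a brute-force enumeration of all
2^(n−1) − 1 bipartitions (not merely sorted splits), on ten thousand fuzzed
vectors.

## Permutation significance and FDR

The null hypothesis is that a set's rows are exchangeable with the rest of
the screen. It is simulated by globally permuting all m × n entries of M and
re-extracting the same r rows. Since only the extracted block matters, each
replicate is drawn equivalently by sampling r·n entries without replacement
from the pooled entries of M — O(r·n) instead of O(m·n) per replicate. For
binary matrices this collapses further: the per-line hit counts of the
sampled block follow an exact multivariate hypergeometric law, which we
sample directly and score in a vectorized pass over all B replicates. The
continuous path keeps the generic value-sampling form. p-values use the
add-one convention p = (1 + #{null ≥ observed}) / (B + 1), B = 1000 by
default, so p is never 0 and the test is valid at finite B.

FDR control uses Storey q-values: π₀ is estimated on the λ grid
0.05, 0.10, …, 0.95 by a cubic smoothing spline extrapolated at the largest
λ, clamped to 1 (with a warning) when the estimate leaves (0, 1] — which
happens routinely for small, discrete p-value collections. With π₀ = 1 the
q-values reduce exactly to Benjamini–Hochberg adjusted p-values. A two-sided
Fisher's exact test on the entries-by-cluster 2 × 2 table
(non-viable/viable × sensitive/resistant), Bonferroni-adjusted over the sets
tested, provides an independent confirmation column.

### Calibration on sparse binary data — a known limit

On a fully null screen (iid Bernoulli hits at rate p₀ = 0.02) the
permutation p-values are **valid but conservative for small sets**, and this
is a property of the statistic, not an implementation artifact. The
bimodality score of a size-5 set takes few distinct values; with 65
Bernoulli(0.02) entries the set has probability ≈ 0.27 of containing no hit
at all, in which case its score is exactly 0, every null replicate ties or
beats it, and p = 1. Consequently:

* pooled p-values across mixed-size null sets are *not* uniform (mass piles
  up near 1); a KS test rejects decisively;
* the mean p-value falls with set size (the discreteness thins out), so the
  Pearson correlation between set size and p-value is visibly negative
  (≈ −0.1 to −0.2) even though **rejection rates** at any level α are below
  α for every size — the test is size-unbiased where it matters, in the
  rejection region;
* within size strata of ≳ 20 members, KS uniformity holds.

The acceptance suite asserts the idealized versions of these properties
(pooled uniformity, |corr| < 0.05) and records their failure; the module
suite asserts the correct ones (conservative validity at every α, stratified
uniformity, size-balanced rejection rates). Users should read q-values on
sparse screens as conservative, and should not interpret the *bulk* p-value
distribution as a calibration check.

A second FDR-semantics point: with 5 strong true positives among 50 sets,
flagging at q ≤ 0.10 *licenses* roughly half a false discovery per screen
(the rank-6 BH cutoff is 0.1 · 6/50 = 0.012, and some decoy crosses it in
roughly a third of simulated screens). "Exactly the planted sets and nothing
else" is therefore not a reasonable expectation at 10% FDR, and the
acceptance suite's corresponding assertion documents this by failing at its
measured rate rather than being weakened.

## Leave-one-out benchmark

The clustering's claim — the sensitive/resistant split generalizes across a
set's members — is tested by withholding one random member per set (sets
with at least `min_size` mapped members, typically 5 or 8), clustering the
training members, and asking whether the withheld gene is hit more in the
sensitive than the resistant lines. The continuous predictor for line j is
the training column mean v_j; the label is the withheld gene's hit in j;
each (set × line) pair is one test instance, pooled within an iteration into
a ROC curve. Sets whose *training* profile fails the permutation test at
q ≤ 0.10 are excluded — prediction is only claimed where training signal is
significant. Curves from `n_iter` iterations are vertically averaged on a
fixed 101-point FPR grid with stepwise-constant interpolation; we report
both the mean of per-iteration trapezoidal AUCs (the headline number, robust
to sparse curve vertices) and the AUC of the averaged curve.

On a fully null screen the gate excludes everything — correctly, but that
makes the calibration of the ROC machinery unmeasurable. `gate_fdr = NULL`
disables the gate for exactly this purpose; so measured, the null mean AUC
is 0.5 within noise, and strongly planted screens (every planted member hit
on exactly the sensitive lines) reach AUC ≈ 1.

## LAS biclustering

Independently of any annotation, Large Average Submatrix biclustering finds
k × l blocks whose average is improbably large under a standard Gaussian
null, scored

$$S(k, l, \text{avg}) = -\log\!\big[\tbinom{m}{k}\tbinom{n}{l}\,
\Phi(-\text{avg}\,\sqrt{kl})\big],$$

computed with log-gamma binomials and the log-scale normal tail (finite for
arbitrarily extreme arguments). The Gaussian score is meaningless on a raw
{0,1} matrix, so inputs are standardized to global mean 0, sd 1 first — for
a binary matrix this is the affine map sending hits to (1−p)/σ. For
continuous essentiality data, where *lower* means more essential, apply the
search to the negated standardized matrix.

The search alternates exact one-sided updates: given the current columns,
every candidate row count k is scanned via sorted partial row sums and the
score-optimal k chosen; symmetrically for columns; iterate to a fixed point,
over `restarts` random column initializations (default 1000; the planted
blocks used in testing are found reliably with under a hundred). Extraction
repeats with residualization — the accepted bicluster's average is
subtracted from its own cells — until the Bonferroni-corrected
p = exp(−S) · (rounds attempted) rises above `alpha` (default 10⁻⁵) or
`max_biclusters` is reached. Two consequences worth knowing: because the
correction multiplies by the round number, p can reach 1 on residualized
noise and halt extraction even at `alpha = 1`; and the score-optimal block
need not equal a planted block — at a +2σ planted signal the optimizer
reliably finds a *higher-scoring* variant that trades the weakest planted
rows for noise rows (row-Jaccard with the plant ≈ 0.8 on average). Both
behaviors are exercised in the tests.

Bicluster genes are annotated by hypergeometric upper-tail enrichment
against a gene-set collection over the screened-gene universe,
BH-adjusted at 5% FDR.

## The per-line hypergeometric product score

For each line, the upper-tail probability of the set's hit count under
Hypergeometric(N = genes screened, K = the line's total hits, n = set size);
the per-line probabilities multiply into one score, handled throughout in
log space (13 lines of p ≈ 10⁻³ would otherwise underflow fast). The same
permutation machinery supplies significance, with one subtlety: this
statistic depends on the permuted matrix's *column totals*, so the binary
null sampler first draws the totals from the exact multivariate
hypergeometric allocation of all hits into columns, then the in-set counts
within each column. This score cannot distinguish a universally toxic set
from a bimodal one — both are extreme — which is precisely why the
clustering score is the primary ranking and this one a documented
comparator. A z-test variant (set mean against the background) is included
only as an internal negative control; screen viabilities are not close to
normal and the z-test inherits the same universal-toxicity blindness.

## Synthetic study conditions

The generator defaults define the desk-scale study: m = 2000 genes,
n = 13 lines, background hit rate p₀ = 0.02, 50 gene sets of 5–30 members,
5 of them planted bimodal with hit probability 0.8 on 4 sensitive lines and
0.05 elsewhere, 4 screening batches. These echo a genome-wide screen on a
13-line panel at a scale where the full pipeline (B = 1000 permutations per
set) runs in seconds; LAS recovery experiments use a 500 × 13 Gaussian
matrix with a planted 20 × 4, 2σ block. What the generator does *not*
emulate: off-target structure correlated across siRNAs, plate spatial
effects beyond batch labels, correlated essentiality between related genes,
or realistic gene-set overlap. Passing tests therefore demonstrate
correctness of the statistics under their stated null and planted-signal
models, not robustness to those real-data pathologies.

One global integer seed governs every random draw; derived seeds (one per
set, per iteration, per round) are generated by a fixed affine map kept
below 2³¹, so all pipeline outputs are bit-reproducible, which the test
suite verifies end to end through the command-line interface.

## Open choices made here

* **Minimum mapped set size**: sets mapping to fewer than 3 screen rows are
  skipped and reported — a 2-means contrast on one or two member genes is
  noise. The threshold is a parameter (`min_mapped`).
* **Unmapped symbols** are reported, never silently dropped; matching is
  exact and case-sensitive.
* **Threshold strictness**: z < −3.0, strict, per the hit-call convention.
* **Permutation scheme**: a single global entry shuffle (not within-row or
  within-column), implemented by its exact sampling equivalents.
* **Sensitive = higher centroid** for hit matrices; for Achilles-convention
  continuous input, negate values if "sensitive" should mean "more
  essential".
* **Fisher confirmation at "10% FDR with Bonferroni"** is implemented as
  Bonferroni-adjusted p ≤ 0.10, the literal composition of the two
  conventions.
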