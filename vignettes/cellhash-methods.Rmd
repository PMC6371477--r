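---
title: "Methods: hashing, indexing, and testing cell search"
author: "cellhash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hashing, indexing, and testing cell search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhash)
```

# The problem

Given a reference collection of single-cell expression profiles (UMI counts,
genes x cells), we want to find, for each query cell, the most similar
reference cells — fast enough to scale to hundreds of thousands of cells and
compact enough that the whole searchable database fits in a single small
file. cellhash does this by reducing each profile to a low-dimensional
vector, hashing it to a short bit string whose Hamming distances estimate
angular similarity, and answering k-nearest-neighbor queries exactly in
Hamming space with multi-index hashing. Label transfer, similarity
estimation, and single-cell differential expression are layered on top.

# Preprocessing

Reference profiles pass through five steps, whose fitted state is stored in
the database and replayed verbatim on queries:

1. **Feature selection.** Genes are kept when their maximum count across
   cells reaches a threshold `t`, with `t` chosen as the largest integer
   retaining at least a fraction (default 10%) of genes. Maximum count is a
   deliberately simple criterion: it is cheap on sparse data and robust, and
   any signal it misses can still be recovered by the later projection.
   Because the search picks the *largest* admissible threshold, the selected
   set sits essentially at the floor — with 20,000 input genes the default
   keeps about 2,000. `keep_genes`/`drop_genes` override the threshold for
   known markers.
2. **Normalization.** Each cell is scaled to a common library size
   (default 10,000 counts — the community convention; any common value
   cancels in the cosine geometry that hashing preserves).
3. **Transform.** `log1p` (default) or the Freeman–Tukey transform
   `sqrt(x) + sqrt(x + 1)`, which stabilizes Poisson variance.
4. **Standardization.** Each selected feature is centered and scaled to
   unit variance (unbiased, n−1 convention). Features whose reference
   standard deviation falls below 1e-8 are dropped with a warning rather
   than allowed to blow up the division; statistics are computed on the
   selected set first and degenerate features removed afterwards.
5. **Projection.** The standardized matrix is reduced to `n_dims` (default
   D = 50) dimensions using the top singular directions from a randomized
   SVD.

Query cells are **folded in**: aligned to the stored feature list by exact
(trimmed) name match — unknown query genes dropped, missing reference genes
zero-filled — then normalized, transformed, standardized with the
*reference* means and variances, and projected with the stored matrix.
Standardizing with reference statistics is what lets a single query cell be
processed at all, and projecting onto the subspace of reference variability
is what absorbs much of the batch difference between experiments. The one
exception is cross-species mapping through homolog tables, where reference
statistics are meaningless for the query's scale; `query_stats = TRUE`
switches to query-side statistics for that case.

# Randomized SVD

`randomized_svd()` is the Halko-style scheme: multiply the (implicitly
centered) matrix by a Gaussian test matrix with 10 extra columns of
oversampling, re-orthonormalize through 3 power iterations, then take the
exact SVD of the small projected matrix. The oversampling and power-iteration
defaults are the standard recommendations; on matrices whose spectrum decays
polynomially the top-10 singular values are recovered to well within 5%
relative error (the acceptance suite checks this on a 2000 x 5000 matrix
with a known spectrum). The `row_offset` argument supports centering sparse
matrices without densifying them. Given a seed the result is bit-for-bit
reproducible.

# Hashing

A signed random projection maps a reduced profile `x` to one bit per
hyperplane: bit i is 1 when the projection on normal `w_i` is strictly
positive (an exactly-zero projection maps to 0; a measure-zero tie, fixed
for determinism). For Gaussian normals, two profiles disagree on a bit with
probability `theta / pi`, so the Hamming distance `d` over `T` bits estimates
the angle as `pi * d / T` and the cosine as `cos(pi * d / T)` — unbiased,
with binomial variance.

To cut that variance, normals are drawn Gaussian and then orthonormalized by
QR in batches of at most D (with the sign convention that keeps the result
equal to Gram–Schmidt of the draws, preserving the distribution of the
frame). Orthogonalization removes the linear dependency between hyperplanes
without introducing bias; with `T <= D` the empirical estimator variance is
strictly smaller for every tested vector pair. When `T > D` exact mutual
orthogonality is impossible, so batches are orthonormalized independently.

Bits are packed little-endian within bytes, bit i belonging to hyperplane i;
this layout is part of the on-disk format.

# Multi-index hashing

Scanning all database codes per query is exact but linear. The single-table
alternative — probing every code within radius `r` of the query — needs
`sum_{i<=r} C(T, i)` bucket probes, which for T = 128 and r = 9 is already
about 20.6 trillion (`search_space_size(128, 9)`). Multi-index hashing
splits each T-bit code into `m = ceiling(T/s)` blocks of `s` bits and
indexes each block in a direct-address subindex of three arrays: a `filled`
bit vector over the 2^s possible subcodes (looked up by ranked popcount),
`offsets`, and a flat `buckets` array of positions.

The query loop expands a radius `r' = 0, 1, 2, ...`; at each radius it
enumerates all subcodes within `r'` flips of each query block, collects the
bucket contents, and verifies candidates with full Hamming distances
(deduplicated per query). By the generalized pigeonhole argument, any vector
not yet seen after radius `r'` differs by more than `r'` in *every* block,
hence its full distance is at least `m * (r' + 1)`; the search stops as soon
as the current k-th best distance beats that bound, so results are exactly
the brute-force answer. The bound is valid for unequal block lengths too:
once `r'` reaches a short block's width, that block has enumerated all its
subcodes and every database vector has been seen through it. Ties at equal
distance order by ascending database position — arbitrary but deterministic.

The default subcode width is `clamp(floor(log2(N)), 8, 16)`: near `log2(N)`
buckets hold O(1) entries each, and the cap at 16 bounds each subindex table
at 2^16 entries. Candidate enumeration generates flip subsets directly;
instruction-level tuning is deliberately out of scope.

# Databases, ranking, and scores

`build_database()` fits the preprocessor, then builds L (default 4)
independent hash indexes of T (default 128) bits; index l uses seed
`seed + l - 1`, so a whole build reproduces from one seed. Longer codes
estimate similarity better but the search space of radius enumeration grows
quickly with T, which is why several shorter independent indexes beat one
long one: each index returns its own k candidates, the union (at most kL
cells) is re-scored by the **total** Hamming distance over all L codes —
computed for every candidate, including those only one index found, since
partial distances would be biased — and the top k by total distance are
returned. Cosine similarities are estimated from the total distance out of
`T * L` bits, which keeps the similarity scale comparable across parameter
choices.

Label transfer is scored by the consistency score (fraction of query cells
whose nearest neighbor carries their label) and Cohen's kappa
`(p_o - p_e) / (1 - p_e)` with expected agreement from the marginal label
frequencies. `self_map_eval()` runs the fivefold protocol: stratified split,
build on four fifths, query the held-out fifth with k = 10, score the
rank-1 neighbor's label.

# Single-cell differential expression

For a query cell `u` matched to database cell `v`, `detect_degs()` retrieves
the k = 10 nearest database neighbors of `v` (in the hashed space, by total
Hamming distance — the same metric the rest of the tool ranks by; `v` is in
the database, so it is always part of its own neighborhood), rescales each
neighbor's raw counts so its total equals `u`'s library size `n_u`, and
averages: `lambda_i` per gene. Under the model `y ~ Pois(beta * lambda)`
with capture efficiencies proportional to totals, this mean is an unbiased
estimate of `u`'s expected counts. Both Poisson tails
`P(Y <= y_i)` and `P(Y >= y_i)` are computed exactly (via the regularized
incomplete-gamma relation inside `ppois`, validated against direct pmf
summation up to `lambda` = 100), and genes with a tail below `alpha`
(default 1e-4) are flagged. Tail probabilities are reported raw — no
multiple-testing correction, matching the method's post hoc screening
intent — so `alpha` should be tightened when many genes or cells are
screened.

Raw counts are kept in a per-cell gzip-compressed store inside the database
(`store_counts = TRUE`); only requested cells are ever decompressed.

**Known limitation — zero neighborhood support.** `lambda` is a plug-in
point estimate. For a gene whose k neighbors all have zero counts,
`lambda = 0` and any query count `y >= 1` receives upper-tail probability
exactly 0, a forced flag at any `alpha`. In sparse data many genes sit in
the expression band (around 0.1 expected counts) where this happens a few
times per thousand genes, so flags on genes with no neighborhood support
should be treated as artifacts of the point estimate, not as evidence.
Calibration claims in the test suite therefore refer to genes with nonzero
neighborhood support; interval estimation of `lambda`, which would fix this
properly, is deliberately out of scope.

# The synthetic generator

All tests run on data from `make_dataset()` / `make_deg_pair()`; nothing is
downloaded. `make_dataset()` draws per-gene base abundances from a
log-normal (sdlog 1.5, giving the several-decade spread of real transcript
abundances), applies multiplicative fold changes at disjoint marker sets
(per-cluster means differ only at markers), assigns per-cell libraries
uniformly in a range, optionally multiplies per-batch log-normal gene-wise
factors, and samples Poisson counts (negative binomial optional, for
robustness checks — UMI counts are well described by Poisson/NB noise
without zero inflation). Defaults — 2,000 genes, 500 cells, 5 clusters,
200 markers per cluster at 4-fold, libraries of 1,000–5,000 counts, batch
scaling sd 0.15 — describe a small, clearly clustered data set.

`make_deg_pair()` draws one homogeneous population plus query cells with a
known gene set shifted by a known fold. Its default libraries are deeper
(5,000–20,000 counts): a spike of 20 genes at several-fold change occupies
15–25% of a shallow library, and the library-size normalization inside the
test then shrinks every gene's effective fold (compositional distortion);
at these depths the spiked mass stays near 5% and the nominal fold is
approximately preserved. Spiked genes are drawn among genes with expected
count >= 8 at the mean library, so the spike acts where a count shift is
observable.

What passing tests on this generator show — and what they do not: clusters
here are separated by clean multiplicative shifts under Poisson noise with
mild multiplicative batch effects. Real data add overdispersion, dropout
structure correlated with expression, ambient RNA, doublets, and batch
effects that are not gene-wise scalings; scores on this generator are an
upper bound on that harder problem, and the near-perfect self-mapping
scores here verify machinery, not biology.

# Numerical and design choices

- Feature threshold search iterates integer thresholds upward and keeps the
  largest that meets the retention floor (integer maxima make it exact).
- Standardization uses n−1 variance; sd < 1e-8 features are dropped.
- `search_space_size()` returns doubles, exact below 2^53 — covering every
  count the tool reports.
- Container files (`save_db`/`load_db`) are sectioned, little-endian, with
  a CRC-32 per section; serialization is deterministic, so equal databases
  produce byte-identical files, and corruption is reported by section name.
  Compressed counts are index-scanned at load but decompressed per cell on
  request.
- Test problem sizes (600–2,000 genes, 150–500 cells, 2,000-code index
  oracles) were chosen as the smallest sizes at which every claim is
  exercised at its advertised tolerance; the acceptance checks use the
  sizes stated above.

# Command line

`inst/cli/cellhash` wraps the same functions as subcommands: `build`,
`search`, `deg`, `info`, `simulate`, `eval`. Outputs are TSV with headers,
probabilities at 6 significant digits.
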