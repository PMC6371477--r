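#' Specification for synthetic clustered UMI data
#'
#' Describes a clustered scRNA-seq-like UMI count matrix: per-gene base
#' abundances drawn from a log-normal, cluster structure expressed as
#' multiplicative fold changes at disjoint marker-gene sets (per-cluster
#' mean vectors differ only at markers), per-cell library sizes, optional
#' per-batch gene-wise scaling, and Poisson (default) or negative-binomial
#' sampling noise.  The defaults describe a small but clearly clustered
#' data set: 2,000 genes, 500 cells, 5 clusters with 200 markers each at a
#' 4-fold change, library sizes of 1,000-5,000 counts.
#'
#' @param n_genes,n_cells matrix dimensions (defaults 2000 x 500).
#' @param n_clusters number of cell clusters (default 5).
#' @param marker_genes_per_cluster markers per cluster, disjoint across
#'   clusters (default 200).
#' @param log2_fold_change log2 fold change applied at markers (default 2,
#'   i.e. 4-fold).
#' @param library_size_range per-cell total-count range, sampled uniformly
#'   (default c(1000, 5000)).
#' @param n_batches number of batches (default 1; set 2+ to add batch
#'   effects).
#' @param batch_scaling_sd sd of the per-batch log-normal gene-wise scaling
#'   (default 0.15; ignored when `n_batches = 1`).
#' @param noise `"poisson"` (default) or `"nb"`.
#' @param nb_dispersion NB dispersion phi in `var = mu (1 + phi mu)`
#'   (default 0.5; only used for `noise = "nb"`).
#' @param seed RNG seed.
#' @return A list of class `SynthSpec`.
#' @export
synth_spec <- function(n_genes = 2000L, n_cells = 500L, n_clusters = 5L,
                       marker_genes_per_cluster = 200L, log2_fold_change = 2,
                       library_size_range = c(1000, 5000), n_batches = 1L,
                       batch_scaling_sd = 0.15,
                       noise = c("poisson", "nb"), nb_dispersion = 0.5,
                       seed = 0L) {
  noise <- match.arg(noise)
  if (n_clusters * marker_genes_per_cluster > n_genes)
    stopf("infeasible spec: %d clusters x %d markers > %d genes",
          n_clusters, marker_genes_per_cluster, n_genes)
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stop("library_size_range must be an increasing positive pair")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
                 log2_fold_change = log2_fold_change,
                 library_size_range = library_size_range,
                 n_batches = as.integer(n_batches),
                 batch_scaling_sd = batch_scaling_sd,
                 noise = noise, nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "SynthSpec")
}

sample_counts <- function(mu, noise, phi) {
  if (noise == "poisson") rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / phi)
}

#' Generate a clustered synthetic UMI matrix with known truth
#'
#' @param spec a [synth_spec()].
#' @return A list with `matrix` (an [expression_matrix()]), `labels`
#'   (cluster label per cell), `batches` (batch label per cell), and
#'   `truth` (base means, per-cluster marker gene sets, batch scaling
#'   factors).
#' @export
make_dataset <- function(spec = synth_spec()) {
  with_seed(spec$seed, {
    G <- spec$n_genes; N <- spec$n_cells; K <- spec$n_clusters
    gene_names <- sprintf("gene%05d", seq_len(G))
    cell_names <- sprintf("cell%05d", seq_len(N))
    base <- rlnorm(G, meanlog = 0, sdlog = 1.5)
    marker_idx <- if (spec$marker_genes_per_cluster > 0L) {
      split(sample.int(G, K * spec$marker_genes_per_cluster),
            rep(seq_len(K), each = spec$marker_genes_per_cluster))
    } else {
      rep(list(integer(0)), K)
    }
    fold <- 2 ^ spec$log2_fold_change
    cluster_means <- matrix(base, G, K)
    for (c in seq_len(K)) cluster_means[marker_idx[[c]], c] <-
      cluster_means[marker_idx[[c]], c] * fold
    labels <- sample(rep_len(seq_len(K), N))
    batches <- sample(rep_len(seq_len(spec$n_batches), N))
    batch_fac <- matrix(1, G, spec$n_batches)
    if (spec$n_batches > 1L)
      batch_fac[] <- exp(rnorm(G * spec$n_batches, 0, spec$batch_scaling_sd))
    libsize <- round(runif(N, spec$library_size_range[1L],
                           spec$library_size_range[2L]))
    counts <- matrix(0, G, N)
    for (j in seq_len(N)) {
      p <- cluster_means[, labels[j]] * batch_fac[, batches[j]]
      mu <- libsize[j] * p / sum(p)
      counts[, j] <- sample_counts(mu, spec$noise, spec$nb_dispersion)
    }
    list(matrix = expression_matrix(counts, gene_names, cell_names),
         labels = paste0("cluster", labels),
         batches = paste0("batch", batches),
         truth = list(base_means = base,
                      markers = lapply(marker_idx, function(i) gene_names[i]),
                      batch_factors = batch_fac,
                      library_sizes = libsize))
  })
}

#' Generate a homogeneous reference plus spiked query cells for DEG testing
#'
#' Draws a single homogeneous cell population (one mean vector, no
#' clusters) as the reference, plus query cells whose means are shifted by
#' `fold` at a known set of genes.  Shifted genes are chosen among genes
#' whose expected count at the mean library size is at least
#' `min_expected`, so the spike acts on genes where a count shift is
#' observable at all.  `fold = 1` (or zero shifted genes) reduces to the
#' null, where any flags are false positives.
#'
#' The default spec uses deeper libraries (5,000-20,000 counts) than
#' [synth_spec()]: a spike of a few dozen genes at several-fold change
#' occupies a non-negligible fraction of a shallow library, and the
#' library-size normalization inside the differential test then shrinks
#' the effective fold change for all genes (compositional distortion).  At
#' these depths the spiked mass stays around 5% of the library and the
#' nominal fold change is approximately preserved.
#'
#' @param spec a [synth_spec()]; `n_cells` sets the reference size and the
#'   noise/library settings are shared by reference and queries.
#' @param shifted_genes how many genes to shift (integer), or explicit gene
#'   names.  May be 0.
#' @param fold multiplicative shift applied in the query cells (default 4).
#' @param n_query number of query cells (default 20).
#' @param min_expected expected-count floor for eligible spike genes
#'   (default 8).
#' @return A list with `reference` and `query` ([expression_matrix()]s) and
#'   `truth` (shifted gene names, fold, direction).
#' @export
make_deg_pair <- function(spec = synth_spec(library_size_range = c(5000, 20000)),
                          shifted_genes = 20L, fold = 4,
                          n_query = 20L, min_expected = 8) {
  with_seed(spec$seed, {
    G <- spec$n_genes
    gene_names <- sprintf("gene%05d", seq_len(G))
    base <- rlnorm(G, meanlog = 0, sdlog = 1.5)
    p <- base / sum(base)
    mean_lib <- mean(spec$library_size_range)
    ref_counts <- matrix(0, G, spec$n_cells)
    libs_ref <- round(runif(spec$n_cells, spec$library_size_range[1L],
                            spec$library_size_range[2L]))
    for (j in seq_len(spec$n_cells))
      ref_counts[, j] <- sample_counts(libs_ref[j] * p, spec$noise,
                                       spec$nb_dispersion)
    if (is.character(shifted_genes)) {
      spike <- match(shifted_genes, gene_names)
      if (anyNA(spike)) stop("unknown gene names in shifted_genes")
    } else if (as.integer(shifted_genes) > 0L) {
      eligible <- which(mean_lib * p >= min_expected)
      if (length(eligible) < shifted_genes)
        stopf("only %d genes reach the expected-count floor %g",
              length(eligible), min_expected)
      spike <- sample(eligible, as.integer(shifted_genes))
    } else {
      spike <- integer(0)
    }
    q_base <- base
    q_base[spike] <- q_base[spike] * fold
    pq <- q_base / sum(q_base)
    qry_counts <- matrix(0, G, n_query)
    libs_q <- round(runif(n_query, spec$library_size_range[1L],
                          spec$library_size_range[2L]))
    for (j in seq_len(n_query))
      qry_counts[, j] <- sample_counts(libs_q[j] * pq, spec$noise,
                                       spec$nb_dispersion)
    list(reference = expression_matrix(ref_counts, gene_names,
                                       sprintf("ref%05d", seq_len(spec$n_cells))),
         query = expression_matrix(qry_counts, gene_names,
                                   sprintf("query%05d", seq_len(n_query))),
         truth = list(shifted_genes = gene_names[spike], fold = fold,
                      direction = if (fold >= 1) "positive" else "negative"))
  })
}
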