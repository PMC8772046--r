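#' Simulate expression-like data from a union of low-dimensional subspaces
#'
#' Generates an m x n matrix whose columns (samples) fall into
#' `n_clusters` classes, each class lying on its own low-dimensional
#' linear subspace of the ambient gene space — the generative assumption
#' of low-rank representation models.  On top of the clean union-of-
#' subspaces signal the generator adds (i) an optional set of salient
#' genes carrying a strong cluster-independent signature -- a constant
#' marker-like offset of magnitude `salient_scale` shared by all samples,
#' the ground truth for gene ranking -- (ii) dense Gaussian noise, and
#' (iii) sparse gross
#' corruption: exactly `round(corruption_frac * m * n)` entries set to
#' +/- `corruption_scale`.
#'
#' Class sizes may be unbalanced (recycle `samples_per_cluster`), mirroring
#' integrated multi-tumor cohorts where one class can be an order of
#' magnitude larger than another.
#'
#' @param n_clusters Number of classes/subspaces.
#' @param subspace_dim Intrinsic dimension per class (recycled).
#' @param samples_per_cluster Samples per class (recycled; may differ).
#' @param ambient_dim Number of genes m (>= sum of subspace dims).
#' @param noise_sigma SD of the dense Gaussian noise.
#' @param corruption_frac Fraction of entries grossly corrupted, in `[0, 1)`.
#' @param corruption_scale Magnitude of corrupted entries.
#' @param n_salient_genes Number of planted salient genes.
#' @param salient_scale Magnitude of the salient signature
#'   (default `5 * noise_sigma`).
#' @param seed Integer seed; the output is fully reproducible from it.
#'
#' @return A list of class `"subspace_sim"`: `X` (m x n matrix with gene
#'   and sample names), `labels` (integer class per sample), `clean_X`
#'   (noise-free union-of-subspaces part, rank <= sum of subspace dims),
#'   `corrupted` (integer indices into `X` of the corrupted entries),
#'   `salient_genes` (row indices of the planted genes) and `spec` (the
#'   arguments).
#' @export
#' @examples
#' sim <- simulate_subspace_data(n_clusters = 3, subspace_dim = 4,
#'                               samples_per_cluster = 60,
#'                               ambient_dim = 200, seed = 0)
#' dim(sim$X)
simulate_subspace_data <- function(n_clusters = 3, subspace_dim = 4,
                                   samples_per_cluster = 60,
                                   ambient_dim = 200,
                                   noise_sigma = 0.05,
                                   corruption_frac = 0.01,
                                   corruption_scale = 1,
                                   n_salient_genes = 0,
                                   salient_scale = 5 * noise_sigma,
                                   seed = 0L) {
  dims <- rep_len(subspace_dim, n_clusters)
  sizes <- rep_len(samples_per_cluster, n_clusters)
  stopifnot(n_clusters >= 1, all(dims >= 1), all(sizes >= 1),
            noise_sigma >= 0, corruption_frac >= 0, corruption_frac < 1,
            corruption_scale > 0, n_salient_genes >= 0)
  m <- ambient_dim
  n <- sum(sizes)
  if (sum(dims) > m) {
    stop("sum of subspace dimensions exceeds 'ambient_dim'", call. = FALSE)
  }
  if (n_salient_genes > m) {
    stop("'n_salient_genes' exceeds 'ambient_dim'", call. = FALSE)
  }

  set.seed(seed)
  blocks <- vector("list", n_clusters)
  for (c_ in seq_len(n_clusters)) {
    basis <- qr.Q(qr(matrix(rnorm(m * dims[c_]), m, dims[c_])))
    coefs <- matrix(rnorm(dims[c_] * sizes[c_]), dims[c_], sizes[c_])
    blocks[[c_]] <- basis %*% coefs
  }
  clean_X <- do.call(cbind, blocks)
  labels <- rep.int(seq_len(n_clusters), sizes)

  X <- clean_X
  salient <- integer(0)
  if (n_salient_genes > 0) {
    salient <- sort(sample.int(m, n_salient_genes))
    # coherent per-gene offset, constant across samples: a marker-like
    # elevation every class shares (a per-entry random pattern would be
    # gross corruption and belongs to P, not the feature component)
    signature <- salient_scale * sample(c(-1, 1), n_salient_genes,
                                        replace = TRUE)
    X[salient, ] <- X[salient, ] + signature
  }
  if (noise_sigma > 0) X <- X + matrix(rnorm(m * n, sd = noise_sigma), m, n)
  n_corrupt <- round(corruption_frac * m * n)
  corrupted <- integer(0)
  if (n_corrupt > 0) {
    corrupted <- sort(sample.int(m * n, n_corrupt))
    X[corrupted] <- corruption_scale *
      sample(c(-1, 1), n_corrupt, replace = TRUE)
  }
  rownames(X) <- rownames(clean_X) <- paste0("gene_", seq_len(m))
  colnames(X) <- colnames(clean_X) <- paste0("sample_", seq_len(n))

  structure(
    list(X = X, labels = labels, clean_X = clean_X, corrupted = corrupted,
         salient_genes = salient,
         spec = list(n_clusters = n_clusters, subspace_dim = dims,
                     samples_per_cluster = sizes, ambient_dim = m,
                     noise_sigma = noise_sigma,
                     corruption_frac = corruption_frac,
                     corruption_scale = corruption_scale,
                     n_salient_genes = n_salient_genes,
                     salient_scale = salient_scale, seed = seed)),
    class = "subspace_sim"
  )
}

#' @export
print.subspace_sim <- function(x, ...) {
  cat(sprintf(
    "Union-of-subspaces simulation: %d genes x %d samples, %d clusters\n",
    nrow(x$X), ncol(x$X), x$spec$n_clusters))
  cat(sprintf(
    "  dims %s | sizes %s | noise sd %g | %d corrupted | %d salient genes\n",
    paste(x$spec$subspace_dim, collapse = "/"),
    paste(x$spec$samples_per_cluster, collapse = "/"),
    x$spec$noise_sigma, length(x$corrupted), length(x$salient_genes)))
  invisible(x)
}

#' PCA reduction of the gene dimension
#'
#' Projects the genes onto the top `d` principal directions of the
#' gene-wise covariance, with samples as observations: genes are centered
#' (optionally after `log2(x + 1)`), the leading `d` left singular vectors
#' of the centered matrix are computed and the data are projected onto
#' them, giving a `d` x n matrix that retains maximal variance.  `d` is
#' capped at the number of nonzero principal components.
#'
#' @param X m x n expression matrix (genes x samples).
#' @param d Target dimension (<= m).
#' @param center Center genes before projecting (default TRUE; required
#'   for a proper PCA).
#' @param log_transform Apply `log2(x + 1)` first (default FALSE; meant
#'   for raw intensity data, not needed for simulated Gaussian data).
#'
#' @return A `d'` x n matrix (`d' = min(d, rank)`), rows named `PC1..`,
#'   with attributes `"variance_retained"` (fraction of total variance)
#'   and `"rotation"` (m x d' matrix of gene loadings).
#' @export
pca_reduce <- function(X, d, center = TRUE, log_transform = FALSE) {
  X <- as_matrix(X)
  check_finite(X, "X")
  m <- nrow(X)
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1) {
    stop("'d' must be a positive integer", call. = FALSE)
  }
  if (d > m) stop("'d' exceeds the number of genes", call. = FALSE)
  if (log_transform) X <- log2(X + 1)
  Xc <- if (center) X - rowMeans(X) else X
  s <- svd(Xc)
  tol <- max(dim(Xc)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  d_eff <- min(as.integer(d), max(rank, 1L))
  V <- s$u[, seq_len(d_eff), drop = FALSE]
  out <- t(V) %*% Xc
  rownames(out) <- paste0("PC", seq_len(d_eff))
  colnames(out) <- colnames(X)
  total_var <- sum(s$d^2)
  attr(out, "variance_retained") <-
    if (total_var > 0) sum(s$d[seq_len(d_eff)]^2) / total_var else 1
  attr(out, "rotation") <- V
  out
}
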