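#' K-means clustering on the low-rank representation
#'
#' Runs K-means `n_runs` times with distinct seeded initializations on the
#' columns of `Z` — each column is the learned representation of one sample
#' — and returns all label vectors so the external indices can be averaged
#' over runs.  By default the samples are embedded by the `n_clusters`
#' leading eigenvectors of the symmetrized affinity `(|Z| + |Z|^T)/2`
#' before K-means -- the spectral-clustering reading standard for low-rank
#' representation affinities, which is far more reliable on signed
#' representations than clustering raw columns.  `affinity = "columns"`
#' clusters the columns of `Z` directly instead.
#'
#' @param Z n x n representation matrix (e.g. `fit$Z`).
#' @param n_clusters Number of clusters (<= n).
#' @param n_runs Number of seeded K-means restarts (default 10).
#' @param seed Base seed; run i uses `seed + i - 1`.
#' @param affinity `"symmetric"` (default, spectral embedding of the
#'   symmetrized affinity) or `"columns"` (cluster columns of `Z`).
#' @param nstart Random initializations per K-means run (each run picks
#'   the best of `nstart` seeded starts, the usual K-means practice).
#'
#' @return A list of `n_runs` integer label vectors of length n.
#' @export
cluster_samples <- function(Z, n_clusters, n_runs = 10L, seed = 1L,
                            affinity = c("symmetric", "columns"),
                            nstart = 10L) {
  Z <- as_matrix(Z)
  check_finite(Z, "Z")
  affinity <- match.arg(affinity)
  n <- ncol(Z)
  if (n_clusters < 1 || n_clusters > n) {
    stop("'n_clusters' must be in 1..n", call. = FALSE)
  }
  feats <- switch(affinity,
    columns = t(Z),
    symmetric = {
      S <- (abs(Z) + t(abs(Z))) / 2
      e <- eigen(S, symmetric = TRUE)
      e$vectors[, seq_len(n_clusters), drop = FALSE]
    }
  )
  lapply(seq_len(n_runs), function(i) {
    set.seed(seed + i - 1L)
    if (n_clusters == 1L) return(rep(1L, n))
    as.integer(stats::kmeans(feats, centers = n_clusters, nstart = nstart,
                             iter.max = 100L)$cluster)
  })
}

# contingency table of two label vectors
label_table <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("'truth' and 'pred' must have equal length", call. = FALSE)
  }
  table(factor(truth), factor(pred))
}

# Hungarian algorithm (augmenting-path / potentials variant) on a square
# cost matrix; returns for each row the assigned column.  Cluster counts
# are tiny so O(k^3) is ample.
hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j+1] = row assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Clustering accuracy by optimal label assignment
#'
#' Fraction of samples whose predicted cluster matches the true class under
#' the best one-to-one mapping between predicted and true labels (the
#' `Map` of the accuracy index), found by solving an optimal assignment on
#' the contingency table with the Hungarian algorithm.
#'
#' @param truth,pred Label vectors of equal length (any atomic type).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' clustering_accuracy(c(0, 0, 1, 1), c(1, 1, 0, 0)) # 1: renaming is free
clustering_accuracy <- function(truth, pred) {
  C <- label_table(truth, pred)
  k <- max(dim(C))
  Cs <- matrix(0, k, k)
  Cs[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  assign <- hungarian(max(Cs) - Cs) # maximize matches
  sum(Cs[cbind(seq_len(k), assign)]) / length(truth)
}

#' Normalized mutual information (max-normalized)
#'
#' Mutual information of the empirical joint label distribution divided by
#' the larger of the two marginal entropies.  When either partition has
#' zero entropy (a single cluster) the index is defined as 0.
#'
#' @param truth,pred Label vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  C <- label_table(truth, pred)
  n <- sum(C)
  pj <- C / n
  pt <- rowSums(pj)
  pp <- colSums(pj)
  Ht <- -sum(ifelse(pt > 0, pt * log(pt), 0))
  Hp <- -sum(ifelse(pp > 0, pp * log(pp), 0))
  if (max(Ht, Hp) == 0) return(0)
  outer_pp <- outer(pt, pp)
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer_pp), 0))
  val <- mi / max(Ht, Hp)
  min(max(val, 0), 1)
}

#' Pairwise F-measure between two partitions
#'
#' Over all unordered sample pairs, counts pairs placed together in both
#' partitions (TP), together only in the prediction (FP) and together only
#' in the truth (FN); returns the harmonic mean of pairwise precision and
#' recall (0 when precision + recall is 0).
#'
#' @param truth,pred Label vectors of equal length (n >= 2).
#' @return A number in `[0, 1]`.
#' @export
pairwise_f_measure <- function(truth, pred) {
  C <- label_table(truth, pred)
  if (length(truth) < 2L) stop("need at least 2 samples", call. = FALSE)
  choose2 <- function(x) sum(x * (x - 1) / 2)
  tp <- choose2(C)
  pairs_pred <- choose2(colSums(C))
  pairs_true <- choose2(rowSums(C))
  fp <- pairs_pred - tp
  fn <- pairs_true - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Rank genes from the feature component
#'
#' Scores gene i by the Euclidean norm of row i of `G %*% X` — the gene's
#' contribution to the salient-feature component `G X` of the
#' reconstruction `X = X Z + G X + P`.  With `method = "rows"` the row
#' norms of `G` itself are used instead.
#'
#' @param G m x m feature matrix (e.g. `fit$G`).
#' @param X The m x n expression matrix the model was fitted to.
#' @param gene_ids Optional gene identifiers; defaults to `rownames(X)` or
#'   `gene_1..gene_m`.
#' @param method `"gx"` (default, row norms of `G X`) or `"rows"` (row
#'   norms of `G`).
#'
#' @return A tibble of class `"gene_ranking"` with columns `gene_id`,
#'   `score` and `rank`, sorted by descending score (ties broken by row
#'   index).
#' @export
score_genes <- function(G, X, gene_ids = NULL, method = c("gx", "rows")) {
  G <- as_matrix(G)
  X <- as_matrix(X)
  method <- match.arg(method)
  m <- nrow(X)
  if (!all(dim(G) == c(m, m))) {
    stop("'G' must be m x m for an m x n 'X'", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(X)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  }
  scores <- switch(method,
    gx = sqrt(rowSums((G %*% X)^2)),
    rows = sqrt(rowSums(G^2))
  )
  ord <- order(-scores, seq_along(scores))
  out <- tibble::tibble(
    gene_id = gene_ids[ord],
    score = scores[ord],
    rank = seq_along(ord),
    row = ord
  )
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Aggregate clustering metrics over repeated runs
#'
#' Computes accuracy, NMI and pairwise F-measure for each run and their
#' mean and population variance (divide by the number of runs), the
#' convention used when clustering results are reported as mean +/-
#' variance over repeats.
#'
#' @param per_run_labels List of predicted label vectors (e.g. from
#'   [cluster_samples()]).
#' @param truth True label vector.
#' @param var_type `"population"` (default) or `"sample"` variance.
#'
#' @return An object of class `"cluster_eval"`: a list with `per_run`
#'   (tibble: run, acc, nmi, f_measure) and `summary` (tibble: metric,
#'   mean, variance, n_runs).
#' @export
aggregate_runs <- function(per_run_labels, truth,
                           var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (length(per_run_labels) < 1L) stop("need at least one run", call. = FALSE)
  per_run <- purrr::map_dfr(seq_along(per_run_labels), function(i) {
    pred <- per_run_labels[[i]]
    tibble::tibble(
      run = i,
      acc = clustering_accuracy(truth, pred),
      nmi = nmi(truth, pred),
      f_measure = pairwise_f_measure(truth, pred)
    )
  })
  pvar <- function(x) {
    if (var_type == "population") mean((x - mean(x))^2) else stats::var(x)
  }
  summary <- tibble::tibble(
    metric = c("acc", "nmi", "f_measure"),
    mean = c(mean(per_run$acc), mean(per_run$nmi), mean(per_run$f_measure)),
    variance = c(pvar(per_run$acc), pvar(per_run$nmi),
                 pvar(per_run$f_measure)),
    n_runs = length(per_run_labels)
  )
  structure(list(per_run = per_run, summary = summary),
            class = "cluster_eval")
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat(sprintf("Clustering evaluation over %d run(s):\n",
              x$summary$n_runs[1]))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$variance[i]))
  }
  invisible(x)
}

#' Cluster a fitted model and evaluate against true labels
#'
#' Convenience wrapper: [cluster_samples()] on `fit$Z` followed by
#' [aggregate_runs()].
#'
#' @param fit A `"tglrr_fit"` object.
#' @param truth True label vector (length n).
#' @param n_clusters Number of clusters; defaults to the number of distinct
#'   true labels.
#' @inheritParams cluster_samples
#' @return A `"cluster_eval"` object (see [aggregate_runs()]).
#' @export
evaluate_clustering <- function(fit, truth, n_clusters = NULL,
                                n_runs = 10L, seed = 1L) {
  stopifnot(inherits(fit, "tglrr_fit"))
  if (is.null(n_clusters)) n_clusters <- length(unique(truth))
  runs <- cluster_samples(fit$Z, n_clusters, n_runs = n_runs, seed = seed)
  aggregate_runs(runs, truth)
}
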