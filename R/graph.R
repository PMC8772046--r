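#' Binary k-nearest-neighbour weights over samples
#'
#' Builds the symmetric 0/1 weight matrix over the columns of `X`: samples
#' i and j are connected when i is among the k nearest neighbours of j *or*
#' j is among the k nearest of i.  Ties in distance are broken by column
#' index, so duplicated samples are handled deterministically.
#'
#' @param X Numeric matrix, features x samples; columns are the data points.
#' @param k Neighbour count, `1 <= k <= ncol(X) - 1`.
#' @param metric Distance between sample columns: `"euclidean"` (default)
#'   or `"cosine"` (one minus cosine similarity).
#'
#' @return An n x n symmetric binary matrix with zero diagonal.
#' @export
knn_weights <- function(X, k, metric = c("euclidean", "cosine")) {
  X <- as_matrix(X)
  check_finite(X, "X")
  metric <- match.arg(metric)
  n <- ncol(X)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 1 || k >= n) {
    stop(sprintf("'k' must be an integer in 1..%d (n - 1)", n - 1L),
         call. = FALSE)
  }
  D <- switch(metric,
    euclidean = {
      g <- crossprod(X)
      sq <- diag(g)
      D2 <- outer(sq, sq, "+") - 2 * g
      D2[D2 < 0] <- 0
      sqrt(D2)
    },
    cosine = {
      nrm <- sqrt(colSums(X^2))
      nrm[nrm == 0] <- 1
      1 - crossprod(sweep(X, 2, nrm, "/"))
    }
  )
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- D[, j]
    d[j] <- Inf
    # order() breaks distance ties by column index
    nb <- order(d)[seq_len(k)]
    W[nb, j] <- 1
  }
  W <- pmax(W, t(W)) # "or" rule; defensive symmetrization
  diag(W) <- 0
  dimnames(W) <- list(colnames(X), colnames(X))
  W
}

#' Sample graph with degree matrix and Laplacian
#'
#' Builds the kNN sample graph of [knn_weights()] together with the degree
#' matrix `O = diag(rowSums(W))` and the (unnormalized) graph Laplacian
#' `L = O - W` used by the manifold penalty of the TGLRR objective.
#'
#' @inheritParams knn_weights
#'
#' @return A list of class `"sample_graph"` with elements `W`, `O`, `L`
#'   and `k`.
#' @export
#' @examples
#' g <- build_graph(matrix(c(0, 1, 10), 1), k = 1)
#' rowSums(g$L) # all zero
build_graph <- function(X, k, metric = c("euclidean", "cosine")) {
  W <- knn_weights(X, k, metric)
  O <- diag(rowSums(W), ncol(W))
  L <- O - W
  dimnames(O) <- dimnames(L) <- dimnames(W)
  out <- list(W = W, O = O, L = L, k = as.integer(k))
  class(out) <- "sample_graph"
  out
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("Sample kNN graph: %d nodes, %d edges, k = %d\n",
              nrow(x$W), sum(x$W) / 2, x$k))
  invisible(x)
}

#' Graph-Laplacian manifold penalty
#'
#' Evaluates \eqn{\mathrm{Tr}(Z L Z^T)}, which equals half the sum of
#' \eqn{w_{ij} \|z_i - z_j\|^2} over sample pairs: representations of
#' neighbouring samples are pushed together.
#'
#' @param Z Numeric matrix whose columns index the graph nodes.
#' @param L An n x n graph Laplacian (or a `"sample_graph"`).
#'
#' @return A non-negative number (up to round-off).
#' @export
graph_penalty <- function(Z, L) {
  if (inherits(L, "sample_graph")) L <- L$L
  Z <- as_matrix(Z)
  L <- as_matrix(L, "L")
  if (ncol(Z) != nrow(L) || nrow(L) != ncol(L)) {
    stop("'L' must be square with dimension ncol(Z)", call. = FALSE)
  }
  sum(diag(Z %*% L %*% t(Z)))
}
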