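# Shared fixtures, generated in code and cached for the session.

# independent singular values via the eigendecomposition of M^T M
# (different LAPACK path than svd(), used as the oracle throughout)
sv_oracle <- function(M) {
  ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(rev(sort(ev))[seq_len(min(dim(M)))], 0))
}

# brute-force scalar proximal operator of tau*|p|: coarse grid search,
# then a fine grid around the coarse minimizer (1e-7 resolution)
prox_l1_grid <- function(m, tau) {
  half <- abs(m) + tau + 1
  g1 <- sort(c(seq(m - half, m + half, length.out = 4001), 0))
  c0 <- g1[which.min(0.5 * (g1 - m)^2 + tau * abs(g1))]
  g2 <- sort(c(seq(c0 - 2e-3, c0 + 2e-3, by = 1e-7), 0))
  g2[which.min(0.5 * (g2 - m)^2 + tau * abs(g2))]
}

# independent SVD built from eigendecompositions, used to cross-check the
# singular value thresholding operator
svt_oracle <- function(M, tau) {
  e <- eigen(M %*% t(M), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  keep <- which(pmax(d - tau, 0) > 0)
  if (!length(keep)) return(matrix(0, nrow(M), ncol(M)))
  U <- e$vectors[, keep, drop = FALSE]
  V <- crossprod(M, U) %*% diag(1 / d[keep], length(keep))
  U %*% diag(d[keep] - tau, length(keep)) %*% t(V)
}

# exhaustive best-bijection clustering accuracy (oracle for the Hungarian)
acc_brute <- function(truth, pred) {
  tl <- unique(truth)
  pl <- unique(pred)
  k <- max(length(tl), length(pl))
  tl <- c(tl, paste0(".t", seq_len(k - length(tl))))
  pl <- c(pl, paste0(".p", seq_len(k - length(pl))))
  best <- 0
  for (perm in asplit(gtools_permutations(k), 1)) {
    mapped <- tl[match(pred, pl[perm])]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  out
}

# the 3-subspace study fixture (shared by the solver-level checks)
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_subspace_data(
        n_clusters = 3, subspace_dim = 4, samples_per_cluster = 60,
        ambient_dim = 200, noise_sigma = 0.05, corruption_frac = 0.01,
        seed = 0)
    }
    cache
  }
})

# one fit on the study fixture, cached across test files
study_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tglrr(study_fixture()$X,
                      control = tglrr_control(eps1 = 1e-3, max_iter = 500))
    }
    cache
  }
})

rand_mat <- function(p, q, seed) {
  set.seed(seed)
  matrix(rnorm(p * q), p, q)
}
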