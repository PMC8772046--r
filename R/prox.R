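#' Elementwise soft-thresholding (shrinkage) operator
#'
#' Proximal operator of the entrywise L1 norm: each entry is moved towards
#' zero by `tau` and clipped at zero.  This is the exact minimizer of
#' \eqn{\tau \|P\|_1 + \tfrac12 \|P - M\|_F^2} and is used for the sparse
#' error block of the TGLRR solver.
#'
#' @param M Numeric matrix (or vector).
#' @param tau Non-negative threshold.
#'
#' @return An object of the same shape as `M` with
#'   `sign(m) * pmax(abs(m) - tau, 0)` applied entrywise.
#' @export
#' @examples
#' soft_threshold(matrix(c(1, -0.3, 0.2, -2), 2), 0.5)
soft_threshold <- function(M, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("'tau' must be a single non-negative number", call. = FALSE)
  }
  check_finite(M, "M")
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Singular value thresholding (SVT) operator
#'
#' Proximal operator of the nuclear norm: soft-thresholds the singular
#' values of `M` while keeping its singular vectors, i.e. returns
#' \eqn{U \,\mathrm{diag}(\max(\sigma_i - \tau, 0))\, V^T}.
#'
#' @param M Numeric matrix.
#' @param tau Non-negative threshold applied to the singular values.
#'
#' @return A matrix of the same shape as `M`.
#' @export
#' @examples
#' svt(diag(c(3, 1, 0.2)), 0.5)
svt <- function(M, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("'tau' must be a single non-negative number", call. = FALSE)
  }
  M <- as_matrix(M)
  check_finite(M, "M")
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) {
    return(matrix(0, nrow(M), ncol(M), dimnames = dimnames(M)))
  }
  out <- s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(M)
  out
}

#' Truncated nuclear norm
#'
#' Sum of the smallest `min(p, q) - r` singular values of `M`: the nuclear
#' norm minus the `r` leading singular values.  With `r = 0` this is the
#' plain nuclear norm; with `r = min(p, q)` it is zero.  Leaving the leading
#' singular values unpenalized gives a tighter surrogate of the rank
#' function than the nuclear norm.
#'
#' @param M Numeric matrix.
#' @param r Truncation level, an integer in `0:min(dim(M))`.
#'
#' @return A single non-negative number.
#' @export
#' @examples
#' truncated_nuclear_norm(diag(3), 1) # 2
truncated_nuclear_norm <- function(M, r) {
  M <- as_matrix(M)
  check_finite(M, "M")
  rmax <- min(dim(M))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r != round(r) ||
      r < 0 || r > rmax) {
    stop(sprintf("'r' must be an integer in 0..%d", rmax), call. = FALSE)
  }
  d <- svd(M, nu = 0, nv = 0)$d
  if (r >= length(d)) 0 else sum(d[(r + 1):length(d)])
}

#' Top-r singular factor pair
#'
#' Computes the factor pair (A, B) of the truncated-nuclear-norm surrogate:
#' `A` holds the `r` leading left singular vectors of `Z` as rows, `B` the
#' `r` leading right singular vectors as rows, so that
#' \eqn{\mathrm{Tr}(A Z B^T) = \sigma_1 + \dots + \sigma_r} and
#' \eqn{\|Z\|_* - \mathrm{Tr}(A Z B^T)} equals the truncated nuclear norm.
#'
#' Sign indeterminacy of singular vectors is resolved deterministically:
#' the entry of largest magnitude of each left singular vector is made
#' positive, and the matching right singular vector is flipped jointly so
#' the trace identity is preserved.
#'
#' @param Z Numeric matrix (p x q).
#' @param r Number of leading singular pairs to keep, in `0:min(dim(Z))`.
#' @param drop_zero Drop pairs whose singular value is numerically zero
#'   (default FALSE); the trace identity is unaffected, but null
#'   directions then contribute no spurious subgradient.
#'
#' @return A list of class `"factor_pair"` with elements `A` (r x p),
#'   `B` (r x q) and `r`.
#' @export
#' @examples
#' fp <- top_r_factors(diag(c(5, 2, 1)), 2)
#' sum(diag(fp$A %*% diag(c(5, 2, 1)) %*% t(fp$B))) # 7
top_r_factors <- function(Z, r, drop_zero = FALSE) {
  Z <- as_matrix(Z)
  check_finite(Z, "Z")
  rmax <- min(dim(Z))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r != round(r) ||
      r < 0 || r > rmax) {
    stop(sprintf("'r' must be an integer in 0..%d", rmax), call. = FALSE)
  }
  r <- as.integer(r)
  if (drop_zero && r > 0L) {
    d <- svd(Z, nu = 0, nv = 0)$d
    r <- min(r, sum(d > max(dim(Z)) * .Machine$double.eps * max(d, 1)))
  }
  if (r == 0L) {
    out <- list(A = matrix(0, 0L, nrow(Z)), B = matrix(0, 0L, ncol(Z)),
                r = 0L)
    class(out) <- "factor_pair"
    return(out)
  }
  s <- svd(Z, nu = r, nv = r)
  U <- s$u
  V <- s$v
  for (i in seq_len(r)) {
    j <- which.max(abs(U[, i]))
    if (U[j, i] < 0) {
      U[, i] <- -U[, i]
      V[, i] <- -V[, i]
    }
  }
  out <- list(A = t(U), B = t(V), r = r)
  class(out) <- "factor_pair"
  out
}

#' Spectral norm (largest singular value)
#'
#' @param M Numeric matrix.
#' @return The largest singular value of `M`.
#' @export
spectral_norm <- function(M) {
  M <- as_matrix(M)
  check_finite(M, "M")
  if (length(M) == 0L) return(0)
  svd(M, nu = 0, nv = 0)$d[1]
}
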