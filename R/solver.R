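#' Solver control parameters
#'
#' Constants of the LADMAP optimizer.  `mu0` is the initial penalty, grown
#' by factor `rho0` (capped at `mu_max`) whenever the iterate changes,
#' weighted by the linearization constants, fall below `eps2` (the adaptive
#' penalty rule).  `eps1` is the relative feasibility tolerance on both
#' constraints `X = XZ + GX + P` and `Z = F`.  `inner_sweeps` is the number
#' of LADMAP sweeps performed per refresh of the truncated-nuclear-norm
#' factor pair (A, B); 1 gives the single-loop schedule, larger values
#' approximate a two-loop scheme with an inner ADMM per fixed (A, B).
#'
#' @param mu0 Initial penalty parameter (> 0).
#' @param mu_max Penalty cap (>= `mu0`).
#' @param rho0 Penalty growth factor (> 1).
#' @param eps1 Relative feasibility tolerance (> 0).
#' @param eps2 Change tolerance driving penalty growth (> 0).
#' @param max_iter Maximum number of outer iterations.
#' @param inner_sweeps LADMAP sweeps per (A, B) refresh (>= 1).
#'
#' @return A list of class `"tglrr_control"`.
#' @export
tglrr_control <- function(mu0 = 1e-2, mu_max = 1e10, rho0 = 1.9,
                          eps1 = 1e-6, eps2 = 10, max_iter = 1000L,
                          inner_sweeps = 1L) {
  stopifnot(mu0 > 0, mu_max >= mu0, rho0 > 1, eps1 > 0, eps2 > 0,
            max_iter >= 1, inner_sweeps >= 1)
  out <- list(mu0 = mu0, mu_max = mu_max, rho0 = rho0, eps1 = eps1,
              eps2 = eps2, max_iter = as.integer(max_iter),
              inner_sweeps = as.integer(inner_sweeps))
  class(out) <- "tglrr_control"
  out
}

#' TGLRR objective value
#'
#' Evaluates the truncated-nuclear-norm low-rank representation objective
#' \deqn{\|Z\|_r + \|G\|_* + \tfrac{\beta}{2}\mathrm{Tr}(Z L Z^T)
#'       + \lambda \|P\|_1,}
#' where \eqn{\|Z\|_r} is the truncated nuclear norm (nuclear norm minus
#' the r leading singular values).
#'
#' @param X Expression matrix, features x samples (used for shape checks).
#' @param Z n x n representation matrix.
#' @param G m x m feature matrix.
#' @param P m x n sparse error matrix.
#' @param L n x n graph Laplacian (or `"sample_graph"`).
#' @param lambda Sparsity weight (>= 0).
#' @param beta Graph weight (>= 0).
#' @param r Truncation level of the nuclear norm on `Z`.
#'
#' @return A single number.
#' @export
tglrr_objective <- function(X, Z, G, P, L, lambda, beta, r) {
  if (inherits(L, "sample_graph")) L <- L$L
  X <- as_matrix(X); Z <- as_matrix(Z); G <- as_matrix(G); P <- as_matrix(P)
  m <- nrow(X); n <- ncol(X)
  if (!all(dim(Z) == c(n, n)) || !all(dim(G) == c(m, m)) ||
      !all(dim(P) == c(m, n)) || !all(dim(L) == c(n, n))) {
    stop("inconsistent shapes among X, Z, G, P, L", call. = FALSE)
  }
  truncated_nuclear_norm(Z, r) +
    sum(svd(G, nu = 0, nv = 0)$d) +
    beta / 2 * graph_penalty(Z, L) +
    lambda * sum(abs(P))
}

# -- LADMAP block updates (one sweep) ------------------------------------
# All updates follow the linearized proximal scheme: each non-smooth block
# minimizes its regularizer plus a quadratic expansion of the smooth part
# of the augmented Lagrangian around the current iterate.

update_Z <- function(Z, F_, G, P, X, L, Y1, Y2, mu, beta, eta1) {
  grad <- beta * (Z %*% L) +
    mu * (Z - F_ + Y2 / mu) +
    mu * crossprod(X, X %*% Z - X + G %*% X + P - Y1 / mu)
  svt(Z - grad / eta1, 1 / (eta1 * mu))
}

update_G <- function(G, Z_new, P, X, Y1, mu, eta2) {
  if (eta2 == 0) return(G) # X = 0: G-subproblem is degenerate, keep iterate
  grad <- mu * (X %*% Z_new - X + G %*% X + P - Y1 / mu) %*% t(X)
  svt(G - grad / eta2, 1 / (eta2 * mu))
}

update_F <- function(Z_new, AB, Y2, mu) {
  if (AB$r == 0L) {
    Z_new + Y2 / mu
  } else {
    Z_new + (crossprod(AB$A, AB$B) + Y2) / mu
  }
}

update_P <- function(Z_new, G_new, X, Y1, mu, lambda) {
  soft_threshold(X - X %*% Z_new - G_new %*% X + Y1 / mu, lambda / mu)
}

update_mu <- function(mu, changes, control) {
  rho <- if (mu * changes <= control$eps2) control$rho0 else 1
  min(control$mu_max, rho * mu)
}

# gradient-ascent step on both multipliers, using the updated penalty
update_multipliers <- function(Y1, Y2, X, Z, G, F_, P, mu) {
  list(Y1 = Y1 + mu * (X - X %*% Z - G %*% X - P),
       Y2 = Y2 + mu * (Z - F_))
}

#' Fit the TGLRR model
#'
#' Solves
#' \deqn{\min_{Z,G,P} \|Z\|_r + \|G\|_* +
#'       \tfrac{\beta}{2}\mathrm{Tr}(Z L Z^T) + \lambda\|P\|_1
#'       \quad \mathrm{s.t.}\; X = X Z + G X + P}
#' by a linearized alternating-direction method with adaptive penalty.
#' Each outer iteration refreshes the factor pair (A, B) from the SVD of
#' the current `Z` (the truncated-nuclear-norm surrogate) and then performs
#' LADMAP sweeps over Z, G, the splitting variable F, and P, followed by
#' the penalty and multiplier updates.  All iterates start at zero and the
#' penalty at `control$mu0`.
#'
#' @param X Expression matrix, features (genes) x samples.
#' @param lambda Sparse-error weight \eqn{\lambda \ge 0}.
#' @param beta Graph-Laplacian weight \eqn{\beta \ge 0}.
#' @param r Truncation level of the nuclear norm on `Z`; `NULL` (default)
#'   picks it from the singular-value curve of `X` via [suggest_r()].
#' @param k_graph Neighbour count of the sample kNN graph.
#' @param graph Optional precomputed [build_graph()] result; overrides
#'   `k_graph`.
#' @param control A [tglrr_control()] list.
#'
#' @return An object of class `"tglrr_fit"`: a list with the converged
#'   `Z` (n x n representation), `G` (m x m feature matrix), `P` (sparse
#'   error), `F` and multipliers, logical `converged`, the iteration
#'   `history` tibble (objective at the iterates, the monitored `loss`
#'   -- the objective with the L1 term evaluated on the actual
#'   reconstruction error `X - XZ - GX`, the quantity whose decrease a
#'   convergence curve shows -- both relative feasibility residuals,
#'   penalty `mu`, change statistic), and the parameters used.
#' @seealso [cluster_samples()] to cluster on `Z`, [score_genes()] to rank
#'   genes from `G`, [tidy()]/[glance()]/[autoplot()] for inspection.
#' @export
#' @examples
#' sim <- simulate_subspace_data(n_clusters = 2, subspace_dim = 2,
#'                               samples_per_cluster = 10, ambient_dim = 30,
#'                               seed = 1)
#' fit <- tglrr(sim$X, r = 2,
#'              control = tglrr_control(max_iter = 50))
#' glance(fit)
tglrr <- function(X, lambda = 0.01, beta = 0.1, r = NULL, k_graph = 5,
                  graph = NULL, control = tglrr_control()) {
  X <- as_matrix(X)
  check_finite(X, "X")
  stopifnot(lambda >= 0, beta >= 0, inherits(control, "tglrr_control"))
  m <- nrow(X)
  n <- ncol(X)
  if (is.null(r)) r <- suggest_r(singular_value_curve(X))
  if (r < 0 || r > n) stop("'r' must be in 0..n", call. = FALSE)
  r <- as.integer(r)

  if (is.null(graph)) graph <- build_graph(X, k = min(k_graph, n - 1L))
  L <- graph$L

  normX2 <- spectral_norm(X)^2
  normL <- spectral_norm(L)
  frobX <- frob(X)
  denom <- max(frobX, .Machine$double.eps)

  Z <- F_ <- Y2 <- matrix(0, n, n)
  G <- matrix(0, m, m)
  P <- Y1 <- matrix(0, m, n)
  mu <- control$mu0
  AB <- top_r_factors(Z, r, drop_zero = TRUE)

  hist_obj <- hist_loss <- hist_res1 <- hist_res2 <- hist_mu <- hist_chg <-
    numeric(control$max_iter)
  converged <- FALSE
  iter <- 0L

  for (k in seq_len(control$max_iter)) {
    if ((k - 1L) %% control$inner_sweeps == 0L) {
      AB <- top_r_factors(Z, r, drop_zero = TRUE)
    }

    eta1 <- beta * normL + mu * (1 + normX2)
    eta2 <- mu * normX2

    Z_new <- update_Z(Z, F_, G, P, X, L, Y1, Y2, mu, beta, eta1)
    G_new <- update_G(G, Z_new, P, X, Y1, mu, eta2)
    F_new <- update_F(Z_new, AB, Y2, mu)
    P_new <- update_P(Z_new, G_new, X, Y1, mu, lambda)

    changes <- max(eta1 * frob(Z_new - Z), eta2 * frob(G_new - G),
                   frob(F_new - F_), frob(P_new - P))
    mu_new <- update_mu(mu, changes, control)

    Ys <- update_multipliers(Y1, Y2, X, Z_new, G_new, F_new, P_new, mu_new)
    Y1 <- Ys$Y1
    Y2 <- Ys$Y2
    R1 <- X - X %*% Z_new - G_new %*% X - P_new
    R2 <- Z_new - F_new

    Z <- Z_new; G <- G_new; F_ <- F_new; P <- P_new; mu <- mu_new
    if (!all(is.finite(Z)) || !all(is.finite(G)) || !all(is.finite(P))) {
      stop(sprintf("solver diverged: non-finite iterate at iteration %d", k),
           call. = FALSE)
    }

    iter <- k
    hist_obj[k] <- tglrr_objective(X, Z, G, P, L, lambda, beta, r)
    # monitored loss: the objective with the sparse term taken on the
    # actual reconstruction error, the quantity convergence curves track
    hist_loss[k] <- hist_obj[k] - lambda * sum(abs(P)) +
      lambda * sum(abs(X - X %*% Z - G %*% X))
    hist_res1[k] <- frob(R1) / denom
    hist_res2[k] <- frob(R2) / denom
    hist_mu[k] <- mu
    hist_chg[k] <- changes

    if (hist_res1[k] <= control$eps1 && hist_res2[k] <= control$eps1) {
      converged <- TRUE
      break
    }
  }

  idx <- seq_len(iter)
  history <- tibble::tibble(
    iteration = idx,
    objective = hist_obj[idx],
    loss = hist_loss[idx],
    residual = hist_res1[idx],
    residual_split = hist_res2[idx],
    mu = hist_mu[idx],
    change = hist_chg[idx]
  )
  structure(
    list(Z = Z, G = G, P = P, F = F_, Y1 = Y1, Y2 = Y2,
         converged = converged, iterations = iter, history = history,
         lambda = lambda, beta = beta, r = r, k_graph = graph$k,
         control = control, dims = c(m = m, n = n),
         sample_ids = colnames(X), gene_ids = rownames(X)),
    class = "tglrr_fit"
  )
}

#' @export
print.tglrr_fit <- function(x, ...) {
  cat(sprintf(
    "TGLRR fit: %d genes x %d samples | lambda = %g, beta = %g, r = %d, k = %d\n",
    x$dims["m"], x$dims["n"], x$lambda, x$beta, x$r, x$k_graph))
  cat(sprintf("%s after %d iterations (residual %.3g, objective %.6g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              x$history$residual[x$iterations],
              x$history$objective[x$iterations]))
  invisible(x)
}

#' Singular-value curve of a matrix
#'
#' All singular values in non-increasing order; plotted against their index
#' this is the scree-like curve whose first inflection guides the choice of
#' the truncation level `r`.
#'
#' @param X Numeric matrix.
#' @return Numeric vector of singular values, largest first.
#' @export
singular_value_curve <- function(X) {
  X <- as_matrix(X)
  check_finite(X, "X")
  svd(X, nu = 0, nv = 0)$d
}

#' Suggest a truncation level from the singular-value curve
#'
#' Deterministic surrogate of reading off the first inflection point of the
#' singular-value curve: returns the index `i` (among the first
#' `min(20, length)` values) maximizing the second difference
#' \eqn{\sigma_i - 2\sigma_{i+1} + \sigma_{i+2}}, i.e. the position after
#' which the curve flattens most abruptly.  Always at least 1; sequences
#' shorter than 3 return 1.  An explicitly supplied `r` in [tglrr()]
#' always takes precedence over this heuristic.
#'
#' @param singular_values Non-increasing numeric vector, e.g. from
#'   [singular_value_curve()].
#' @return A positive integer.
#' @export
#' @examples
#' suggest_r(c(100, 90, 5, 4, 3)) # 2
suggest_r <- function(singular_values) {
  d <- singular_values
  if (length(d) < 3L) return(1L)
  if (any(diff(d) > 1e-8 * max(abs(d), 1))) {
    stop("'singular_values' must be non-increasing", call. = FALSE)
  }
  imax <- min(20L, length(d))
  i_ok <- seq_len(min(imax, length(d) - 2L))
  curv <- d[i_ok] - 2 * d[i_ok + 1L] + d[i_ok + 2L]
  as.integer(which.max(curv))
}
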