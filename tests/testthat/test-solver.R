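# small consistent random state for update-level checks
make_state <- function(m = 5, n = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(m * n), m, n)
  g <- build_graph(X, 2)
  list(X = X, L = g$L, graph = g,
       Z = matrix(rnorm(n * n), n, n), F_ = matrix(rnorm(n * n), n, n),
       G = matrix(rnorm(m * m), m, m), P = matrix(rnorm(m * n), m, n),
       Y1 = matrix(rnorm(m * n), m, n), Y2 = matrix(rnorm(n * n), n, n))
}

test_that("objective assembles its four terms", {
  st <- make_state()
  zero <- function(a, b) matrix(0, a, b)
  expect_equal(
    tglrr_objective(st$X, zero(6, 6), zero(5, 5), zero(5, 6), st$L,
                    lambda = 1, beta = 1, r = 2), 0)
  # r = 0, beta = 0 reduces to nuclear + nuclear + L1
  red <- tglrr_objective(st$X, st$Z, st$G, st$P, st$L, 0.3, 0, 0)
  expect_equal(red, sum(sv_oracle(st$Z)) + sum(sv_oracle(st$G)) +
                 0.3 * sum(abs(st$P)), tolerance = 1e-8)
  # term-by-term oracle with independent SVDs and double-loop penalty
  pen <- 0
  W <- st$graph$W
  for (i in 1:6) for (j in 1:6) {
    pen <- pen + W[i, j] * sum((st$Z[, i] - st$Z[, j])^2)
  }
  d <- sv_oracle(st$Z)
  expect_equal(
    tglrr_objective(st$X, st$Z, st$G, st$P, st$L, 0.4, 1.7, 2),
    (sum(d) - d[1] - d[2]) + sum(sv_oracle(st$G)) + 1.7 / 2 * pen / 2 +
      0.4 * sum(abs(st$P)),
    tolerance = 1e-8)
  expect_error(tglrr_objective(st$X, st$Z[, -1], st$G, st$P, st$L, 1, 1, 0),
               "shapes")
})

test_that("Z update reduces to SVT at a stationary point", {
  st <- make_state(seed = 2)
  # zero gradient: beta = 0, F = Z, Y2 = 0, P the exact residual, Y1 = 0
  P0 <- st$X - st$X %*% st$Z - st$G %*% st$X
  mu <- 0.7
  eta1 <- mu * (1 + spectral_norm(st$X)^2)
  out <- tglrr:::update_Z(st$Z, st$Z, st$G, P0, st$X, st$L,
                          0 * st$Y1, 0 * st$Y2, mu, beta = 0, eta1 = eta1)
  expect_equal(out, svt(st$Z, 1 / (eta1 * mu)), tolerance = 1e-10)
})

test_that("Z update matches the scalar prox on a 1x1 problem", {
  x <- 2; z <- 0.4; f <- -0.3; g <- 0.5; p <- 0.1
  y1 <- 0.2; y2 <- -0.7; mu <- 1.3; beta <- 0.9
  L <- matrix(0, 1, 1) # single sample: no edges
  eta1 <- beta * 0 + mu * (1 + x^2)
  grad <- beta * z * 0 + mu * (z - f + y2 / mu) +
    mu * x * (x * z - x + g * x + p - y1 / mu)
  arg <- z - grad / eta1
  expect_equal(
    tglrr:::update_Z(matrix(z, 1, 1), matrix(f, 1, 1), matrix(g, 1, 1),
                     matrix(p, 1, 1), matrix(x, 1, 1), L,
                     matrix(y1, 1, 1), matrix(y2, 1, 1), mu, beta, eta1),
    matrix(sign(arg) * max(abs(arg) - 1 / (eta1 * mu), 0), 1, 1),
    tolerance = 1e-12)
})

test_that("Z and G updates decrease their linearized surrogates", {
  st <- make_state(seed = 3)
  mu <- 0.5
  eta1 <- 0.8 * spectral_norm(st$L) + mu * (1 + spectral_norm(st$X)^2)
  Zn <- tglrr:::update_Z(st$Z, st$F_, st$G, st$P, st$X, st$L, st$Y1, st$Y2,
                         mu, beta = 0.8, eta1 = eta1)
  gradZ <- 0.8 * st$Z %*% st$L + mu * (st$Z - st$F_ + st$Y2 / mu) +
    mu * crossprod(st$X, st$X %*% st$Z - st$X + st$G %*% st$X + st$P -
                     st$Y1 / mu)
  surr <- function(Znew) {
    sum(sv_oracle(Znew)) / (eta1 * mu) +
      0.5 * sum((Znew - (st$Z - gradZ / eta1))^2)
  }
  expect_lte(surr(Zn), surr(st$Z) + 1e-10)

  eta2 <- mu * spectral_norm(st$X)^2
  Gn <- tglrr:::update_G(st$G, Zn, st$P, st$X, st$Y1, mu, eta2)
  gradG <- mu * (st$X %*% Zn - st$X + st$G %*% st$X + st$P - st$Y1 / mu) %*%
    t(st$X)
  surrG <- function(Gnew) {
    sum(sv_oracle(Gnew)) / (eta2 * mu) +
      0.5 * sum((Gnew - (st$G - gradG / eta2))^2)
  }
  expect_lte(surrG(Gn), surrG(st$G) + 1e-10)
})

test_that("G update gradient has the outer-product support pattern", {
  st <- make_state(seed = 4)
  X <- matrix(0, 5, 6)
  X[, 3] <- rnorm(5) # single nonzero sample column
  mu <- 0.9
  R <- X %*% st$Z - X + st$G %*% X + st$P - st$Y1 / mu
  grad <- mu * R %*% t(X)
  expect_equal(grad, mu * outer(R[, 3], X[, 3]), tolerance = 1e-12)
  # zero-residual case collapses to SVT of the iterate
  eta2 <- mu * spectral_norm(st$X)^2
  P0 <- st$X - st$X %*% st$Z - st$G %*% st$X
  out <- tglrr:::update_G(st$G, st$Z, P0, st$X, 0 * st$Y1, mu, eta2)
  expect_equal(out, svt(st$G, 1 / (eta2 * mu)), tolerance = 1e-10)
})

test_that("F update solves its subproblem exactly", {
  st <- make_state(seed = 5)
  mu <- 1.1
  AB <- top_r_factors(st$Z, 2)
  Fn <- tglrr:::update_F(st$Z, AB, st$Y2, mu)
  # finite-difference gradient of the F-subproblem objective is ~ 0
  obj <- function(F_) {
    -sum(diag(AB$A %*% F_ %*% t(AB$B))) + sum(st$Y2 * (st$Z - F_)) +
      mu / 2 * sum((st$Z - F_)^2)
  }
  h <- 1e-6
  for (idx in list(c(1, 1), c(3, 4), c(6, 2))) {
    Fp <- Fn; Fp[idx[1], idx[2]] <- Fp[idx[1], idx[2]] + h
    Fm <- Fn; Fm[idx[1], idx[2]] <- Fm[idx[1], idx[2]] - h
    expect_lt(abs((obj(Fp) - obj(Fm)) / (2 * h)), 1e-6)
  }
  # r = 0: surrogate term absent
  AB0 <- top_r_factors(st$Z, 0)
  expect_equal(tglrr:::update_F(st$Z, AB0, st$Y2, mu), st$Z + st$Y2 / mu)
  # large mu, Y2 = 0: F -> Z
  expect_equal(tglrr:::update_F(st$Z, AB, 0 * st$Y2, 1e12), st$Z,
               tolerance = 1e-10)
})

test_that("P update is the shrinkage of the reconstruction error", {
  st <- make_state(seed = 6)
  mu <- 0.8
  arg <- st$X - st$X %*% st$Z - st$G %*% st$X + st$Y1 / mu
  expect_equal(tglrr:::update_P(st$Z, st$G, st$X, st$Y1, mu, lambda = 0),
               arg)
  out <- tglrr:::update_P(st$Z, st$G, st$X, st$Y1, mu, lambda = 0.6)
  oracle <- apply(arg, c(1, 2), prox_l1_grid, tau = 0.6 / mu)
  expect_equal(out, oracle, tolerance = 1e-6)
})

test_that("multiplier and penalty updates follow their definitions", {
  st <- make_state(seed = 7)
  # zero residuals leave multipliers unchanged
  P0 <- st$X - st$X %*% st$Z - st$G %*% st$X
  upd <- tglrr:::update_multipliers(st$Y1, st$Y2, st$X, st$Z, st$G, st$Z,
                                    P0, mu = 2)
  expect_equal(upd$Y1, st$Y1, tolerance = 1e-12)
  expect_equal(upd$Y2, st$Y2, tolerance = 1e-12)
  # unit residual in one entry increments that multiplier entry by mu
  P1 <- P0; P1[2, 3] <- P1[2, 3] - 1
  upd1 <- tglrr:::update_multipliers(st$Y1, st$Y2, st$X, st$Z, st$G, st$Z,
                                     P1, mu = 1)
  expect_equal(upd1$Y1[2, 3], st$Y1[2, 3] + 1)
  # random-state definitional check
  upd2 <- tglrr:::update_multipliers(st$Y1, st$Y2, st$X, st$Z, st$G, st$F_,
                                     st$P, mu = 0.4)
  expect_equal(upd2$Y1, st$Y1 +
                 0.4 * (st$X - st$X %*% st$Z - st$G %*% st$X - st$P))
  expect_equal(upd2$Y2, st$Y2 + 0.4 * (st$Z - st$F_))

  ctl <- tglrr_control(rho0 = 1.5, eps2 = 1, mu_max = 10)
  expect_equal(tglrr:::update_mu(2, changes = 0.4, ctl), 3) # fires
  expect_equal(tglrr:::update_mu(2, changes = 10, ctl), 2)  # holds
  expect_equal(tglrr:::update_mu(10, changes = 0, ctl), 10) # capped
})

test_that("the zero matrix is a one-iteration fixed point", {
  fit <- tglrr(matrix(0, 6, 5), r = 1, control = tglrr_control(max_iter = 10))
  expect_true(fit$converged)
  expect_identical(fit$iterations, 1L)
  expect_true(all(fit$Z == 0) && all(fit$G == 0) && all(fit$P == 0))
  expect_equal(fit$history$objective[1], 0)
})

test_that("the solver reaches feasibility on multi-subspace data", {
  fit <- study_fit()
  expect_true(fit$converged)
  expect_lte(fit$iterations, 500)
  h <- fit$history
  expect_lte(h$residual[nrow(h)], 1e-3)
  expect_lte(h$residual_split[nrow(h)], 1e-3)
  # the monitored loss decreases from its initial value and is
  # non-increasing over (at least) 90% of the final half
  expect_lt(h$loss[nrow(h)], h$loss[1])
  lh <- h$loss[(floor(nrow(h) / 2) + 1):nrow(h)]
  expect_gte(mean(diff(lh) <= 1e-9 * pmax(abs(lh[-length(lh)]), 1)), 0.9)
  # overall residual trend: the running minimum keeps improving
  expect_lt(min(h$residual[(nrow(h) - 4):nrow(h)]),
            min(h$residual[1:floor(nrow(h) / 2)]))
})

test_that("an extreme sparsity weight forces the error matrix to zero", {
  sm <- simulate_subspace_data(2, 2, 12, 40, noise_sigma = 0.05,
                               corruption_frac = 0.02, seed = 3)
  fit <- tglrr(sm$X, lambda = 1e8,
               control = tglrr_control(eps1 = 1e-3, max_iter = 800))
  expect_equal(max(abs(fit$P)), 0)
  expect_lt(tail(fit$history$residual, 1), 1e-2)
})

test_that("fixed-penalty and two-loop schedules still reach feasibility", {
  sm <- simulate_subspace_data(2, 2, 12, 40, noise_sigma = 0.02,
                               corruption_frac = 0, seed = 3)
  fit <- tglrr(sm$X, control = tglrr_control(mu0 = 1, mu_max = 1,
                                             rho0 = 1 + 1e-9, eps1 = 1e-3,
                                             max_iter = 2000))
  expect_true(fit$converged)
  fit2 <- tglrr(sm$X, control = tglrr_control(eps1 = 1e-3, max_iter = 500,
                                              inner_sweeps = 5))
  expect_true(fit2$converged)
})

test_that("fitting is deterministic", {
  sm <- simulate_subspace_data(2, 2, 10, 30, seed = 9)
  f1 <- tglrr(sm$X, control = tglrr_control(eps1 = 1e-3, max_iter = 200))
  f2 <- tglrr(sm$X, control = tglrr_control(eps1 = 1e-3, max_iter = 200))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$Z, f2$Z)
})

test_that("non-convergence within max_iter is reported, not thrown", {
  sm <- simulate_subspace_data(2, 2, 10, 30, seed = 9)
  fit <- tglrr(sm$X, control = tglrr_control(max_iter = 2))
  expect_false(fit$converged)
  expect_identical(nrow(fit$history), 2L)
})

test_that("singular value curve and truncation suggestion", {
  expect_equal(singular_value_curve(diag(c(5, 2, 1))), c(5, 2, 1))
  set.seed(15)
  r1 <- outer(rnorm(6), rnorm(4))
  expect_equal(sum(singular_value_curve(r1) > 1e-10), 1)
  M <- rand_mat(6, 5, 16)
  expect_equal(singular_value_curve(M), sv_oracle(M), tolerance = 1e-10)

  expect_identical(suggest_r(c(100, 90, 5, 4, 3)), 2L)
  expect_identical(suggest_r(100 * 0.5^(1:10)), 1L)
  expect_identical(suggest_r(c(10, 1, 1, 1)), 1L)
  expect_identical(suggest_r(c(3, 1)), 1L)
  expect_error(suggest_r(c(1, 2, 3)), "non-increasing")
})
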