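test_that("soft-thresholding has the exact proximal form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- c(-2.5, 0, 4)
  expect_equal(soft_threshold(z, 0), z)
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("the rotated system implements the covariance-bound weights", {
  # tau = 0: flat weights 1/4 and no profiling
  n <- 12
  km0 <- pglmmlasso:::.km_zero(n)
  X <- cbind(1, rnorm(n))
  rs0 <- build_rotated(list(tau = 0), km0, X)
  expect_equal(rs0$w, rep(0.25, n))
  expect_equal(rs0$s, rep(0, n))
  # huge eigenvalues: s -> 1, w -> 0
  V <- diag(n) * 1e8
  km_big <- eigendecompose_kinship(V, 1)
  rs_big <- build_rotated(list(tau = 1), km_big, X)
  expect_true(all(rs_big$s > 1 - 1e-6))
  expect_true(all(rs_big$w < 1e-6))
  # the identity s = 1 - c * w links shrinkage and weights
  md <- make_mm_data(n = 20, p = 8, p_kin = 60, seed = 51)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  km <- eigendecompose_kinship(md$V, null$tau)
  rs <- build_rotated(null, km, cbind(md$sim$X, md$G))
  expect_equal(rs$s, 1 - 4 * rs$w, tolerance = 1e-12)
  # dense-inverse oracle: X*' diag(w) X* = X' (4I + tau V)^{-1} X
  Xf <- cbind(md$sim$X, md$G)
  lhs <- crossprod(rs$Xstar, rs$Xstar * rs$w)
  rhs <- crossprod(Xf, solve(diag(4, 20) + null$tau * md$V, Xf))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("profiling the random effects matches the dense normal equations", {
  # tau = 0 gives b = 0
  n <- 15
  km0 <- pglmmlasso:::.km_zero(n)
  X <- cbind(1, rnorm(n))
  rs0 <- build_rotated(list(tau = 0), km0, X)
  expect_equal(profile_b(rs0, c(0.5, -1), rnorm(n))$b, rep(0, n))

  # scalar case: V = I, tau = c shrinks the working response by c/(4+c)
  cc <- 1.7
  km1 <- eigendecompose_kinship(diag(n), cc)
  rs1 <- build_rotated(list(tau = cc), km1, X)
  yt <- rnorm(n)
  pb <- profile_b(rs1, c(0, 0), drop(crossprod(km1$U, yt)))
  expect_equal(pb$b, (cc / (4 + cc)) * yt, tolerance = 1e-10)

  # general case: direct minimizer of the ridge-penalized quadratic
  set.seed(52)
  V <- random_psd(n) + diag(0.1, n)
  tau <- 0.8
  km <- eigendecompose_kinship(V, tau)
  rs <- build_rotated(list(tau = tau), km, X)
  beta <- c(0.3, -0.6)
  offset <- drop(X %*% beta)
  pb2 <- profile_b(rs, beta, drop(crossprod(km$U, yt)))
  # oracle: argmin_b (yt - offset - b)' (I/4) (yt - offset - b) + b' K^{-1} b / 2
  K <- tau * V
  b_oracle <- drop(K %*% solve(diag(4, n) + K, yt - offset))
  expect_equal(pb2$b, b_oracle, tolerance = 1e-8)
})

test_that("the penalty grid brackets the first active predictor", {
  md <- make_mm_data(n = 80, p = 40, p_kin = 150, seed = 53)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  km <- eigendecompose_kinship(md$V, null$tau)
  path <- pglmm_path(null, km, md$G, nlambda = 5,
                     lambda.min.ratio = 0.95)
  # at lambda_max the penalized active set is empty
  expect_identical(path$n_active[1], 0L)
  # just below lambda_max at least one SNP activates
  path2 <- pglmm_path(null, km, md$G,
                      lambda = path$lambda_max * c(1, 0.99))
  expect_identical(path2$n_active[1], 0L)
  expect_gte(path2$n_active[2], 1L)
  # homogeneity: doubling all penalty factors halves lambda_max
  path3 <- pglmm_path(null, km, md$G,
                      penalty.factor = rep(2, ncol(md$G)), nlambda = 2,
                      lambda.min.ratio = 0.95)
  expect_equal(path3$lambda_max, path$lambda_max / 2, tolerance = 1e-10)
})

test_that("coordinate descent reaches the proximal-gradient optimum", {
  set.seed(54)
  reps <- 5
  for (r in seq_len(reps)) {
    n <- 30
    p <- 10
    X <- cbind(1, rnorm(n))
    G <- standardize_genotypes(matrix(rbinom(n * p, 2, runif(p, .2, .4)),
                                      n, p, byrow = FALSE))
    V <- random_psd(n) + diag(0.05, n)
    y <- rbinom(n, 1, plogis(rnorm(n)))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    tau <- runif(1, 0.2, 1.5)
    null <- pglmmlasso:::.null_fixed_tau(X, y)
    null$tau <- tau
    km <- eigendecompose_kinship(V, tau)
    path <- pglmm_path(null, km, G, nlambda = 12, lambda.min.ratio = 0.05,
                       tol_outer = 1e-12, maxit_outer = 500, tol_cd = 1e-9)
    v <- c(rep(0, ncol(X)), rep(1, ncol(G)))
    for (k in c(4L, 8L, 12L)) {
      oracle <- prox_grad_oracle(cbind(X, G), y, km$U, km$eigvals,
                                 path$lambda[k], v)
      expect_equal(unname(path$coef[, k]), unname(oracle$beta),
                   tolerance = 1e-5)
    }
  }
})

test_that("with tau = 0 the path solves the plain logistic lasso", {
  skip_if_not_installed("glmnet")
  set.seed(55)
  n <- 150
  p <- 30
  G <- standardize_genotypes(matrix(rbinom(n * p, 2, 0.3), n, p))
  y <- rbinom(n, 1, plogis(-0.5 + G[, 1] - 0.8 * G[, 2]))
  null <- pglmmlasso:::.null_fixed_tau(cbind(rep(1, n)), y)
  km0 <- pglmmlasso:::.km_zero(n)
  path <- pglmm_path(null, km0, G, nlambda = 10, lambda.min.ratio = 0.1,
                     tol_outer = 1e-12, maxit_outer = 500, tol_cd = 1e-9)
  gn <- glmnet::glmnet(G, y, family = "binomial", standardize = FALSE,
                       lambda = path$lambda / n, thresh = 1e-14)
  ours <- path$coef
  theirs <- rbind(gn$a0, as.matrix(gn$beta))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-5)
})

test_that("a nearly unpenalized low-dimensional fit matches plain logistic estimates", {
  set.seed(56)
  n <- 200
  G <- standardize_genotypes(matrix(rbinom(n * 3, 2, 0.3), n, 3))
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * G[, 1] - 0.5 * G[, 2]))
  null <- pglmmlasso:::.null_fixed_tau(cbind(rep(1, n)), y)
  km0 <- pglmmlasso:::.km_zero(n)
  path <- pglmm_path(null, km0, G, nlambda = 2, lambda.min.ratio = 1e-4,
                     tol_outer = 1e-12, maxit_outer = 500)
  glmfit <- glm.fit(cbind(1, G), y, family = binomial())
  expect_equal(unname(path$coef[, 2]), unname(glmfit$coefficients),
               tolerance = 0.02)
})

test_that("the Gaussian-family path solves the penalized linear mixed model", {
  set.seed(57)
  n <- 40
  p <- 12
  X <- cbind(rep(1, n))
  G <- standardize_genotypes(matrix(rbinom(n * p, 2, 0.3), n, p))
  V <- random_psd(n) + diag(0.1, n)
  tau <- 0.7
  b <- drop(chol(tau * V) %*% rnorm(n))
  yg <- drop(0.5 + G[, 1] * 0.8 + b + rnorm(n))
  null <- structure(list(alpha = 0, tau = tau, phi = 1, X = X, y = yg),
                    class = "NullFit")
  km <- eigendecompose_kinship(V, tau)
  path <- pglmm_path(null, km, G, family = "gaussian", phi = 1,
                     nlambda = 8, lambda.min.ratio = 0.05, tol_cd = 1e-10)
  v <- c(0, rep(1, p))
  for (k in c(3L, 6L, 8L)) {
    oracle <- prox_grad_oracle(cbind(X, G), yg, km$U, km$eigvals,
                               path$lambda[k], v, family = "gaussian")
    expect_equal(unname(path$coef[, k]), unname(oracle$beta),
                 tolerance = 1e-6)
  }
})

test_that("every reported solution satisfies the KKT conditions", {
  md <- make_mm_data(n = 100, p = 50, p_kin = 200, seed = 58)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  km <- eigendecompose_kinship(md$V, null$tau)
  path <- suppressWarnings(
    pglmm_path(null, km, md$G, nlambda = 20, lambda.min.ratio = 0.05)
  )
  Xf <- cbind(md$sim$X, md$G)
  rs <- build_rotated(null, km, Xf)
  pen_idx <- which(path$penalty.factor > 0)
  # the outer loop is allowed to flag non-convergence deep into the
  # overfitting region; KKT is guaranteed at every converged solution
  expect_gte(sum(path$converged), length(path$lambda) - 3L)
  for (k in which(path$converged)) {
    beta <- path$coef[, k]
    # surrogate gradient at the reported solution and working response
    grad <- drop(crossprod(rs$Xstar, rs$w * path$rstar[, k]))
    lamv <- path$lambda[k] * path$penalty.factor
    inact <- pen_idx[beta[pen_idx] == 0]
    act <- pen_idx[beta[pen_idx] != 0]
    expect_true(all(abs(grad[inact]) <= lamv[inact] + 1e-6))
    if (length(act)) {
      expect_lt(max(abs(abs(grad[act]) - lamv[act])), 1e-6)
    }
    # at the fixed point the surrogate gradient equals the true-likelihood
    # gradient X'(y - mu); check consistency on the active set
    eta <- drop(Xf %*% beta) + path$b[, k]
    mu <- plogis(eta)
    grad_true <- drop(crossprod(Xf, md$sim$y - mu))
    if (length(act)) {
      expect_equal(grad[act], grad_true[act], tolerance = 1e-2)
    }
  }
  expect_identical(path$n_active[1], 0L)
})

test_that("the curvature bound dominates the true working covariance", {
  md <- make_mm_data(n = 60, p = 30, p_kin = 120, seed = 59)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  expect_lte(max(null$mu * (1 - null$mu)), 0.25)
  # W <= I/4 in the PSD order, so the surrogate covariance 4I + tau V is
  # dominated by the true working covariance W^{-1} + tau V
  Sigma <- diag(1 / null$W) + null$tau * md$V
  Sigma_b <- diag(4, nrow(md$V)) + null$tau * md$V
  ev <- eigen(Sigma - Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("the profiled surrogate objective never increases across CD sweeps", {
  md <- make_mm_data(n = 60, p = 30, p_kin = 120, seed = 60)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  km <- eigendecompose_kinship(md$V, null$tau)
  Xf <- cbind(md$sim$X, md$G)
  rs <- build_rotated(null, km, Xf)
  ystar <- drop(crossprod(km$U, null$Ytilde))
  q <- ncol(Xf)
  v <- c(rep(0, ncol(md$sim$X)), rep(1, ncol(md$G)))
  lam <- 0.05 * max(abs(crossprod(rs$Xstar, rs$w * ystar)))
  beta <- numeric(q)
  r <- ystar
  obj_prev <- Inf
  for (sweep in 1:25) { # one sweep at a time via maxit = 1
    res <- pglmmlasso:::cd_inner(rs$Xstar, rs$w, r, beta, rs$xtx, v, lam,
                                 seq_len(q) - 1L, 0, 1L)
    beta <- res$beta
    r <- res$r
    obj <- profiled_surrogate(r, rs$w, rs$s, beta, v, lam)
    expect_lte(obj, obj_prev + 1e-10)
    obj_prev <- obj
  }
})

test_that("solutions vary continuously along a refined penalty grid", {
  md <- make_mm_data(n = 80, p = 40, p_kin = 150, seed = 61)
  null <- fit_null_pglmm(md$sim$X, md$sim$y, md$V)
  km <- eigendecompose_kinship(md$V, null$tau)
  coarse <- pglmm_path(null, km, md$G, nlambda = 5, lambda.min.ratio = 0.3)
  fine <- pglmm_path(null, km, md$G, nlambda = 41, lambda.min.ratio = 0.3)
  # the coarse path is embedded in the fine one
  for (k in seq_along(coarse$lambda)) {
    kf <- which.min(abs(fine$lambda - coarse$lambda[k]))
    expect_equal(coarse$coef[, k], fine$coef[, kf], tolerance = 0.02)
  }
  steps <- apply(abs(diff(t(fine$coef))), 1, max)
  expect_lt(max(steps), 0.5) # no jumps on a fine grid
})

test_that("adaptive weights follow the marginal-coefficient power law", {
  set.seed(62)
  n <- 150
  p <- 12
  G <- standardize_genotypes(matrix(rbinom(n * p, 2, 0.3), n, p))
  X <- cbind(rep(1, n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * G[, 3]))
  expect_equal(adaptive_weights(G, X, y, kappa = 0), rep(1, p))
  v1 <- adaptive_weights(G, X, y, kappa = 1)
  v2 <- adaptive_weights(G, X, y, kappa = 2)
  # direct per-SNP check of v_j = |beta_hat_j|^{-kappa}
  for (j in c(1L, 3L, 7L)) {
    bj <- glm.fit(cbind(X, G[, j]), y,
                  family = binomial())$coefficients[2]
    expect_equal(v1[j], min(abs(bj)^-1, 1e6), tolerance = 1e-8)
    expect_equal(v2[j], min(abs(bj)^-2, 1e6), tolerance = 1e-8)
  }
  # the strongly causal SNP is penalized least
  expect_equal(which.min(v1), 3L)
})

test_that("a causal SNP receives systematically smaller adaptive weight than null SNPs", {
  set.seed(63)
  wins <- 0
  for (r in 1:10) {
    n <- 120
    p <- 8
    G <- standardize_genotypes(matrix(rbinom(n * p, 2, 0.3), n, p))
    y <- rbinom(n, 1, plogis(-0.3 + 1.5 * G[, 1]))
    if (length(unique(y)) < 2) next
    v <- adaptive_weights(G, cbind(rep(1, n)), y, kappa = 1)
    if (v[1] < median(v[-1])) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
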