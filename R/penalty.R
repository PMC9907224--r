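#' Adaptive lasso penalty factors from marginal regressions
#'
#' Fits, for each SNP, the univariable logistic regression of the phenotype on
#' the covariates plus that standardized SNP, and converts the SNP coefficient
#' into a penalty factor `v_j = |beta_hat_j|^(-kappa)`. `kappa = 0` recovers
#' the plain lasso (all factors 1). Marginal fits that separate (non-finite or
#' exploding coefficients) fall back to a ridge-stabilized Newton fit.
#'
#' @param G `n x p` standardized SNP matrix or a [genotype_data()] object.
#' @param X covariate matrix including the intercept.
#' @param y binary response in `{0,1}`.
#' @param kappa nonnegative adaptive-lasso power (default 1).
#' @param cap upper cap on the factors (default `1e6`).
#' @return Length-`p` vector of penalty factors.
#' @export
adaptive_weights <- function(G, X, y, kappa = 1, cap = 1e6) {
  if (kappa < 0) stop("kappa must be nonnegative")
  if (inherits(G, "GenotypeData")) G <- standardize_genotypes(G)
  G <- as.matrix(G)
  p <- ncol(G)
  if (kappa == 0) return(rep(1, p))
  X <- as.matrix(X)
  beta_marg <- numeric(p)
  for (j in seq_len(p)) {
    Xj <- cbind(X, G[, j])
    fit <- suppressWarnings(
      stats::glm.fit(Xj, y, family = stats::binomial())
    )
    bj <- fit$coefficients[ncol(Xj)]
    if (!is.finite(bj) || abs(bj) > 20 || !fit$converged) {
      bj <- .ridge_logistic(Xj, y)[ncol(Xj)]
      message("marginal fit for SNP ", j,
              " separated; ridge-stabilized coefficient used")
    }
    beta_marg[j] <- bj
  }
  pmin(abs(beta_marg)^(-kappa), cap)
}

# Newton iterations for logistic regression with a small L2 penalty,
# used when the unpenalized marginal fit separates.
.ridge_logistic <- function(X, y, ridge = 1e-2, maxit = 50L) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- .clip_mu(.expit(eta))
    Wv <- mu * (1 - mu)
    H <- crossprod(X, X * Wv) + diag(ridge, ncol(X))
    g <- crossprod(X, y - mu) - ridge * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  beta
}
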