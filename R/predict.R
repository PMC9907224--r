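#' Mixed-model prediction for new individuals
#'
#' Predicts case probabilities for a test set by the conditional expectation
#' of the working response given the training data,
#' `mu_s = expit(Xs beta_hat + tau1 V12 (W^{-1} + tau1 V1)^{-1}
#' (Ytilde - X beta_hat))`,
#' evaluated with the same curvature-bound weights `W = I / c` used during
#' fitting, so that training-set self-prediction reproduces the fitted linear
#' predictor. Under the bound the kinship BLUP projection reduces to
#' per-eigencomponent shrinkage `tau1 / (c + tau1 Lambda_i)`, reusing the one
#' spectral decomposition. A single variance component (the GRM) is required.
#'
#' @param path a [pglmm_path()] object fitted on the training set.
#' @param null the training [fit_null_pglmm()] object.
#' @param km the training [eigendecompose_kinship()] object (`S = 1`).
#' @param Xs `n_s x (m + p)` test design: covariates (same columns as the
#'   training `null$X`) followed by test genotypes standardized with the
#'   training MAFs.
#' @param V12 `n_s x n` cross-similarity from [cross_grm()].
#' @param which_lambda integer index (or vector of indices) into the path;
#'   default all.
#' @return Matrix `n_s x length(which_lambda)` of probabilities, with the
#'   linear predictors in attribute `eta` and the genetic random-effect
#'   component in attribute `eta_re`.
#' @export
predict_mixed <- function(path, null, km, Xs, V12, which_lambda = NULL) {
  if (length(km$tau) > 1L) {
    stop("mixed-model prediction supports a single variance component ",
         "(S = 1); got S = ", length(km$tau))
  }
  if (is.null(which_lambda)) which_lambda <- seq_along(path$lambda)
  Xs <- as.matrix(Xs)
  if (ncol(Xs) != nrow(path$coef)) {
    stop("test design has ", ncol(Xs), " columns; training fit has ",
         nrow(path$coef))
  }
  tau1 <- km$tau[1]
  wshrink <- tau1 / (path$c_bound + km$eigvals) # tau1/(c + tau1 * Lambda_i)
  # Ytilde - X beta = U rstar, so the BLUP term is V12 U (wshrink * rstar)
  re_rot <- km$U %*% (wshrink * path$rstar[, which_lambda, drop = FALSE])
  eta_re <- V12 %*% re_rot
  eta_fix <- Xs %*% path$coef[, which_lambda, drop = FALSE]
  eta <- eta_fix + eta_re
  out <- .expit(eta)
  attr(out, "eta") <- eta
  attr(out, "eta_re") <- eta_re
  out
}

#' Principal-component GLM prediction for new individuals
#'
#' The fixed-effect alternative to kinship-based prediction: the confounding
#' signal is captured by the top `r` principal components of the training
#' GRM, whose coefficients are the generalized-least-squares solution on the
#' partial working residuals,
#' `delta = (Ur' W Ur)^{-1} Ur' W (Ytilde - X beta_hat)`,
#' and test subjects receive the projected component scores `V12 Ur`:
#' `mu_s = expit(Xs beta_hat + V12 Ur delta)`. Unlike the mixed model, which
#' shrinks every component smoothly by its eigenvalue, this keeps the first
#' `r` components unshrunk and discards the rest.
#'
#' @param beta coefficient vector for the training design `Xfull`.
#' @param Xfull training `n x (m + p)` design the coefficients refer to.
#' @param Ytilde training working response at those coefficients.
#' @param W length-`n` working weights (e.g. `rep(1/4, n)` for the logistic
#'   curvature bound, or the final IRLS weights).
#' @param U training GRM eigenvector matrix.
#' @param r number of leading components to use (`0` gives the
#'   fixed-effects-only prediction).
#' @param Xs test design (same columns as `Xfull`).
#' @param V12 `n_s x n` cross-similarity matrix.
#' @return List with `prob`, `eta` and `delta` (the `r` component
#'   coefficients).
#' @export
predict_pc_glm <- function(beta, Xfull, Ytilde, W, U, r, Xs, V12) {
  if (r < 0 || r > ncol(U)) stop("r must be between 0 and n")
  resid <- Ytilde - drop(as.matrix(Xfull) %*% beta)
  eta <- drop(as.matrix(Xs) %*% beta)
  delta <- numeric(0)
  if (r > 0) {
    Ur <- U[, seq_len(r), drop = FALSE]
    M <- crossprod(Ur, Ur * W)
    if (rcond(M) < 1e-12) stop("singular weighted PC cross-product")
    delta <- drop(solve(M, crossprod(Ur, W * resid)))
    eta <- eta + drop(V12 %*% Ur %*% delta)
  }
  list(prob = .expit(eta), eta = eta, delta = delta)
}

#' Assemble a test-set design aligned with a training fit
#'
#' Standardizes test genotypes with the training MAFs (restricted to the SNP
#' columns the training path used) and binds them to the test covariates.
#'
#' @param X_test test covariate matrix (same columns as the training
#'   `null$X`).
#' @param g_test test [genotype_data()] object.
#' @param g_train training [genotype_data()] object used to fit the path.
#' @return Numeric test design matrix `[X_test, G_test_standardized]`.
#' @export
make_test_design <- function(X_test, g_test, g_train) {
  idx <- match(g_train$variants$id, g_test$variants$id)
  if (anyNA(idx)) stop("test set lacks training variants")
  gs <- standardize_genotypes(g_test$counts[, idx, drop = FALSE],
                              maf = g_train$maf)
  cbind(as.matrix(X_test), gs)
}
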