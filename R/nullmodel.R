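#' @useDynLib pglmmlasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# logistic helpers; mu is clipped away from {0,1} so working quantities stay
# finite even at saturated linear predictors.
.expit <- function(eta) stats::plogis(eta)
.clip_mu <- function(mu, eps = 1e-10) pmin(pmax(mu, eps), 1 - eps)

#' One penalized quasi-likelihood working update (logit link)
#'
#' Given a binary response and linear predictor, forms the IRLS working
#' weights `W = mu (1 - mu)` and working response
#' `Ytilde = eta + (y - mu) / W` of the logistic mixed model.
#'
#' @param y binary response in `{0,1}`.
#' @param eta linear predictor.
#' @return List with `mu`, `W` and `Ytilde`.
#' @export
working_update <- function(y, eta) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  mu <- .clip_mu(.expit(eta))
  W <- mu * (1 - mu)
  list(mu = mu, W = W, Ytilde = eta + (y - mu) / W)
}

#' Fit the logistic mixed model under the null (no SNP effects)
#'
#' Estimates covariate effects and variance components of the GLMM
#' `logit(mu) = X alpha + b`, `b ~ N(0, sum_s tau_s V_s)`, by penalized
#' quasi-likelihood: the binary response is linearized into a working response
#' and the variance components of the resulting working linear mixed model are
#' updated by average-information REML, alternating with updates of the fixed
#' effects and of the random-effect predictions. The fitted `tau` is then held
#' fixed for the whole regularization path (the "population parameters
#' previously determined" two-step strategy).
#'
#' @param X `n x m` covariate matrix of full column rank, including an
#'   intercept column.
#' @param y binary response in `{0,1}` containing both classes.
#' @param Vs a single PSD similarity matrix or list of them (the first is
#'   conventionally the GRM).
#' @param tol convergence tolerance on the maximum relative change of
#'   `(alpha, tau)` (default `1e-5`).
#' @param maxit maximum number of outer iterations (default 100).
#' @param verbose print the variance-component trajectory.
#' @return Object of class `NullFit`: `alpha` (covariate effects), `tau`
#'   (variance components), `phi` (dispersion, fixed at 1 for the binomial
#'   family), `b` (random-effect predictions), `eta`, `mu`, `W`, `Ytilde`,
#'   `converged`, `n_iter`, `trace` (per-iteration `tau`), plus the inputs
#'   `X` and `y` for downstream stages.
#' @export
fit_null_pglmm <- function(X, y, Vs, tol = 1e-5, maxit = 100L,
                           verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.matrix(Vs)) Vs <- list(Vs)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions differ")
  if (!all(y %in% c(0, 1))) stop("y must be binary in {0,1}")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  S <- length(Vs)
  for (V in Vs) {
    if (nrow(V) != n || ncol(V) != n) stop("similarity matrix is not n x n")
  }

  # warm start: plain logistic fit, then GMMAT-style tau initialization
  glm0 <- stats::glm.fit(X, y, family = stats::binomial())
  alpha <- glm0$coefficients
  eta <- drop(X %*% alpha)
  wu <- working_update(y, eta)
  tau <- rep(0.1 * stats::var(wu$Ytilde) / S, S)
  floor_tau <- 1e-6 * stats::var(wu$Ytilde)
  trace <- matrix(NA_real_, 0, S)
  converged <- FALSE
  b <- numeric(n)
  rel <- Inf

  for (it in seq_len(maxit)) {
    alpha_old <- alpha
    tau_old <- tau

    # working linear mixed model at the current (alpha, b)
    Sigma <- diag(1 / wu$W, n)
    for (s in seq_len(S)) Sigma <- Sigma + tau[s] * Vs[[s]]
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) stop("working covariance not positive definite at ",
                          "iteration ", it)
    Sigma_inv <- chol2inv(ch)
    SiX <- Sigma_inv %*% X
    XtSiX <- crossprod(X, SiX)
    XtSiX_inv <- solve(XtSiX)
    P <- Sigma_inv - SiX %*% XtSiX_inv %*% t(SiX)
    Py <- drop(P %*% wu$Ytilde)

    # REML score at the *current* state (the one returned on convergence)
    score <- numeric(S)
    VsPy <- vector("list", S)
    for (s in seq_len(S)) {
      VsPy[[s]] <- drop(Vs[[s]] %*% Py)
      score[s] <- 0.5 * (sum(Py * VsPy[[s]]) - sum(P * Vs[[s]]))
    }
    # declare convergence only when both the parameter change of the previous
    # sweep and the score at the present state are small (a clamped component
    # may legitimately keep a negative score at the boundary)
    ok_score <- all(ifelse(tau > floor_tau * 1.001,
                           abs(score) < 5e-4 * n, score < 5e-4 * n))
    if (rel < tol && ok_score) {
      converged <- TRUE
      break
    }

    # AI-REML step on tau
    AI <- matrix(0, S, S)
    for (s in seq_len(S)) {
      PVsPy <- drop(P %*% VsPy[[s]])
      for (t in s:S) {
        AI[s, t] <- AI[t, s] <- 0.5 * sum(VsPy[[t]] * PVsPy)
      }
    }
    delta <- tryCatch(solve(AI, score), error = function(e) score / diag(AI))
    step <- 1
    tau_new <- tau + delta
    for (h in seq_len(12)) {
      if (all(is.finite(tau_new)) && all(tau_new > -floor_tau)) break
      step <- step / 2
      tau_new <- tau + step * delta
    }
    tau <- pmax(tau_new, floor_tau)
    if (any(!is.finite(tau))) {
      stop("AI-REML diverged (non-finite tau) at iteration ", it,
           "; trace:\n", paste(apply(trace, 1, paste, collapse = " "),
                               collapse = "\n"))
    }

    # fixed effects and random-effect predictions at the new tau
    Sigma <- diag(1 / wu$W, n)
    for (s in seq_len(S)) Sigma <- Sigma + tau[s] * Vs[[s]]
    Sigma_inv <- chol2inv(chol(Sigma))
    SiX <- Sigma_inv %*% X
    alpha <- drop(solve(crossprod(X, SiX), crossprod(SiX, wu$Ytilde)))
    resid <- wu$Ytilde - drop(X %*% alpha)
    K <- matrix(0, n, n)
    for (s in seq_len(S)) K <- K + tau[s] * Vs[[s]]
    b <- drop(K %*% (Sigma_inv %*% resid))

    trace <- rbind(trace, tau)
    if (verbose) {
      message("iter ", it, ": tau = ",
              paste(format(tau, digits = 5), collapse = ", "))
    }

    rel <- max(abs(c(alpha - alpha_old, tau - tau_old)) /
                 pmax(abs(c(alpha_old, tau_old)), 1e-8))
    eta <- drop(X %*% alpha) + b
    wu <- working_update(y, eta)
  }

  structure(
    list(alpha = alpha, tau = tau, phi = 1, b = b, eta = eta, mu = wu$mu,
         W = wu$W, Ytilde = wu$Ytilde, converged = converged,
         n_iter = nrow(trace), trace = trace, X = X, y = y,
         floor_tau = floor_tau),
    class = "NullFit"
  )
}

#' @export
print.NullFit <- function(x, ...) {
  cat("Null logistic mixed model (PQL / AI-REML)\n")
  cat("  tau:", paste(format(x$tau, digits = 5), collapse = ", "),
      if (all(x$tau <= x$floor_tau * 1.0001)) "(at lower clamp)" else "", "\n")
  cat("  alpha:", paste(format(x$alpha, digits = 4), collapse = ", "), "\n")
  cat("  iterations:", x$n_iter, if (x$converged) "(converged)"
      else "(NOT converged)", "\n")
  invisible(x)
}

#' Serialize / restore a null fit as plain CSV files
#'
#' Writes scalars (`tau`, `phi`, `alpha`, convergence info) and per-sample
#' vectors to `<prefix>_params.csv` and `<prefix>_samples.csv` so a fitted
#' null model can be reused by the path stage in a separate process.
#'
#' @param fit a [fit_null_pglmm()] object.
#' @param prefix output path prefix.
#' @export
write_null_fit <- function(fit, prefix) {
  params <- data.frame(
    name = c(paste0("tau", seq_along(fit$tau)), "phi",
             paste0("alpha", seq_along(fit$alpha)), "converged", "n_iter"),
    value = c(fit$tau, fit$phi, fit$alpha, as.numeric(fit$converged),
              fit$n_iter)
  )
  utils::write.csv(params, paste0(prefix, "_params.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(b = fit$b, eta = fit$eta, mu = fit$mu, W = fit$W,
               Ytilde = fit$Ytilde, y = fit$y),
    paste0(prefix, "_samples.csv"), row.names = FALSE
  )
  invisible(prefix)
}
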