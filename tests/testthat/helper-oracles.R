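# Independent oracles used to cross-check the fitting code. These solve the
# same optimization problems by entirely different algorithms (accelerated
# proximal gradient, dense linear algebra, grid search) and share no code
# with the package internals.

# Accelerated proximal-gradient (FISTA with restart) minimizer of the
# penalized quasi-likelihood objective
#   Q(beta, delta) = loss(eta) + 0.5 * sum(delta^2 / d_pos) +
#                    lambda * sum(v |beta|),
# eta = Xfull beta + U_pos delta, jointly over the fixed effects and the
# rotated random effects (restricted to the positive-eigenvalue range of the
# random-effect covariance). For family = "binomial" the loss is the
# Bernoulli negative log-likelihood; for "gaussian" it is 0.5 ||y - eta||^2
# / phi. Returns the fixed-effect vector at the optimum.
prox_grad_oracle <- function(Xfull, y, U, d, lambda, v,
                             family = c("binomial", "gaussian"), phi = 1,
                             tol = 1e-12, maxit = 2e5) {
  family <- match.arg(family)
  Xfull <- as.matrix(Xfull)
  n <- nrow(Xfull)
  q <- ncol(Xfull)
  pos <- which(d > 1e-12)
  Upos <- U[, pos, drop = FALSE]
  dpos <- d[pos]
  M <- cbind(Xfull, Upos)
  curv <- if (family == "binomial") 0.25 else 1 / phi
  L <- curv * max(eigen(crossprod(M), symmetric = TRUE,
                        only.values = TRUE)$values)
  if (length(pos)) L <- L + max(1 / dpos)
  step <- 1 / L

  grad_loss_eta <- function(eta) {
    if (family == "binomial") stats::plogis(eta) - y else (eta - y) / phi
  }
  obj <- function(beta, delta) {
    eta <- drop(Xfull %*% beta) + if (length(pos)) drop(Upos %*% delta) else 0
    loss <- if (family == "binomial") {
      -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    } else {
      0.5 * sum((y - eta)^2) / phi
    }
    loss + 0.5 * sum(delta^2 / dpos) + lambda * sum(v * abs(beta))
  }

  beta <- numeric(q)
  delta <- numeric(length(pos))
  zb <- beta
  zd <- delta
  tk <- 1
  obj_old <- obj(beta, delta)
  for (it in seq_len(maxit)) {
    eta <- drop(Xfull %*% zb) + if (length(pos)) drop(Upos %*% zd) else 0
    ge <- grad_loss_eta(eta)
    gb <- drop(crossprod(Xfull, ge))
    beta_new <- zb - step * gb
    thr <- step * lambda * v
    beta_new <- sign(beta_new) * pmax(abs(beta_new) - thr, 0)
    if (length(pos)) {
      gd <- drop(crossprod(Upos, ge)) + zd / dpos
      delta_new <- zd - step * gd
    } else {
      delta_new <- delta
    }
    obj_new <- obj(beta_new, delta_new)
    if (obj_new > obj_old) { # restart the momentum
      tk <- 1
      zb <- beta
      zd <- delta
      next
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb <- beta_new + ((tk - 1) / t_new) * (beta_new - beta)
    zd <- delta_new + ((tk - 1) / t_new) * (delta_new - delta)
    move <- max(abs(c(beta_new - beta, delta_new - delta)))
    beta <- beta_new
    delta <- delta_new
    tk <- t_new
    if (move < tol && it > 10) break
    obj_old <- obj_new
  }
  list(beta = beta, delta = delta, objective = obj(beta, delta))
}

# Restricted (REML) log-likelihood of the working linear mixed model
# Ytilde = X alpha + b + e, e ~ N(0, W^{-1}), b ~ N(0, tau V),
# up to an additive constant. Used for grid-search verification of the
# AI-REML estimate.
working_reml_loglik <- function(tau, Ytilde, design, W, V) {
  X <- design
  n <- length(Ytilde)
  Sigma <- diag(1 / W, n) + tau * V
  ch <- chol(Sigma)
  Sigma_inv <- chol2inv(ch)
  XtSiX <- crossprod(X, Sigma_inv %*% X)
  P <- Sigma_inv -
    Sigma_inv %*% X %*% solve(XtSiX, t(X) %*% Sigma_inv)
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                       as.numeric(determinant(XtSiX)$modulus) +
                       drop(t(Ytilde) %*% P %*% Ytilde)))
}

# random PSD matrix with unit-scale diagonal
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n, 2 * n)
  V <- tcrossprod(A) / (2 * n)
  (V + t(V)) / 2
}
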