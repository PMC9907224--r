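#' Soft-thresholding operator
#'
#' The proximal operator of the absolute value:
#' `sign(z) * max(|z| - t, 0)`.
#'
#' @param z numeric.
#' @param t nonnegative threshold.
#' @return numeric of the same length as `z`.
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop("threshold must be nonnegative")
  sign(z) * pmax(abs(z) - t, 0)
}

#' Rotate the working model by the kinship eigenvectors
#'
#' For a binary trait the IRLS weights satisfy `mu (1 - mu) <= 1/4`, so the
#' working-response covariance `Sigma = W^{-1} + sum_s tau_s V_s` is dominated
#' (in the PSD order) by the fixed surrogate `Sigma_b = c I + sum_s tau_s V_s`
#' with `c = 4`. Because `Sigma_b` does not depend on the weights, a single
#' eigendecomposition `sum_s tau_s V_s = U diag(d) U'` rotates the whole path:
#' in rotated coordinates the surrogate is diagonal with effective weights
#' `w_i = 1/(c + d_i)` and random-effect profiling factors
#' `s_i = d_i / (c + d_i)`.
#'
#' For a Gaussian trait (`c = phi`) no bound is involved and the same algebra
#' is exact.
#'
#' @param null a [fit_null_pglmm()] object (only `tau` is needed here; pass
#'   a list with a `tau` element for synthetic setups).
#' @param km a [eigendecompose_kinship()] object built from the same `tau`.
#' @param Xfull the full `n x (m + p)` design `[X, G]` in original
#'   coordinates.
#' @param c_bound curvature constant replacing `W^{-1}`: 4 for the logistic
#'   bound, `phi` for a Gaussian working model.
#' @return Object of class `RotatedSystem`: `Xstar = U' Xfull`, `w`, `s`,
#'   `d`, `U`, `c_bound`, and `xtx` (`sum_i w_i Xstar[i,j]^2` per column).
#' @export
build_rotated <- function(null, km, Xfull, c_bound = 4) {
  Xfull <- as.matrix(Xfull)
  if (nrow(Xfull) != nrow(km$U)) stop("design and kinship dimensions differ")
  d <- km$eigvals
  w <- 1 / (c_bound + d)
  s <- d / (c_bound + d)
  Xstar <- crossprod(km$U, Xfull)
  xtx <- drop(crossprod(Xstar^2, w))
  structure(
    list(Xstar = Xstar, w = w, s = s, d = d, U = km$U, c_bound = c_bound,
         xtx = xtx),
    class = "RotatedSystem"
  )
}

#' Profile the random effects out of the rotated working model
#'
#' At fixed coefficients the random-effect predictions have the closed form
#' `bstar_i = s_i (ystar_i - Xstar_i beta)` in rotated coordinates; in the
#' original coordinates `b = U bstar`.
#'
#' @param rs a [build_rotated()] object.
#' @param beta current coefficient vector (length `ncol(Xstar)`).
#' @param ystar rotated working response `U' Ytilde`.
#' @return List with `bstar` (rotated) and `b` (original coordinates).
#' @export
profile_b <- function(rs, beta, ystar) {
  bstar <- rs$s * (ystar - drop(rs$Xstar %*% beta))
  list(bstar = bstar, b = drop(rs$U %*% bstar))
}

# log-spaced penalty grid from lambda_max down to ratio * lambda_max
.lambda_grid <- function(lambda_max, nlambda, lambda_min_ratio) {
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}
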