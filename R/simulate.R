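#' Configuration for the structured-population simulation design
#'
#' Defaults reproduce the first simulation scenario of the method's study
#' conditions: n = 2500 admixed individuals from K = 10 subpopulations on a
#' 1D geographic gradient, 5000 candidate SNPs of which 1% are causal, a
#' separate 50 000-SNP panel for the kinship matrix, half of the liability
#' variance from fixed SNP effects and 40% from a confounded polygenic random
#' effect, and a 10% prevalence under the null.
#'
#' @param n sample size.
#' @param p number of candidate SNPs.
#' @param p_kinship number of extra SNPs reserved for the GRM/PC panel.
#' @param c fraction of candidate SNPs that are causal.
#' @param K number of subpopulations.
#' @param structure `"admix_1d"` (individuals spread along a 1D geography
#'   with Gaussian admixture kernels) or `"independent"` (K disjoint equal
#'   blocks).
#' @param h_g2 fraction of liability variance from fixed causal-SNP effects.
#' @param h_b2 fraction of liability variance from the polygenic random
#'   effect.
#' @param pi0 prevalence under the null model.
#' @param F per-subpopulation Balding-Nichols drift parameters (default
#'   linearly spaced 0.05 to 0.2).
#' @param sigma_geo kernel width of the 1D admixture geography.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n = 2500L, p = 5000L, p_kinship = 50000L, c = 0.01,
                       K = 10L, structure = c("admix_1d", "independent"),
                       h_g2 = 0.5, h_b2 = 0.4, pi0 = 0.1,
                       F = seq(0.05, 0.2, length.out = K), sigma_geo = 1.0) {
  structure <- match.arg(structure)
  if (h_g2 + h_b2 >= 1) stop("h_g2 + h_b2 must be < 1")
  if (c <= 0 || c > 1) stop("causal fraction must be in (0, 1]")
  if (pi0 <= 0 || pi0 >= 1) stop("pi0 must be in (0, 1)")
  if (length(F) != K || any(F <= 0) || any(F >= 1)) {
    stop("F must hold K drift values in (0, 1)")
  }
  if (sigma_geo <= 0) stop("sigma_geo must be positive")
  structure(
    list(n = as.integer(n), p = as.integer(p),
         p_kinship = as.integer(p_kinship), c = c, K = as.integer(K),
         structure = structure, h_g2 = h_g2, h_b2 = h_b2, pi0 = pi0,
         F = F, sigma_geo = sigma_geo),
    class = "SimConfig"
  )
}

# admixture proportion matrix (n x K) for a configuration
.admixture_q <- function(cfg) {
  if (cfg$structure == "admix_1d") {
    x <- seq(1, cfg$K, length.out = cfg$n)
    Q <- outer(x, seq_len(cfg$K),
               function(xi, u) exp(-(xi - u)^2 / (2 * cfg$sigma_geo^2)))
    Q / rowSums(Q)
  } else {
    block <- sort(rep(seq_len(cfg$K), length.out = cfg$n))
    Q <- matrix(0, cfg$n, cfg$K)
    Q[cbind(seq_len(cfg$n), block)] <- 1
    Q
  }
}

#' Simulate structured genotypes from the Balding-Nichols admixture model
#'
#' Draws, per SNP, an ancestral frequency `p_anc ~ Uniform(0.01, 0.5)`,
#' per-subpopulation frequencies from the Balding-Nichols distribution
#' `Beta(p_anc (1-F_u)/F_u, (1-p_anc)(1-F_u)/F_u)`, and genotypes
#' `Binomial(2, pi_ij)` with `pi_ij = sum_u q_iu p_uj` given the admixture
#' proportions. SNPs whose sample MAF falls below 0.01 are redrawn so the
#' panel contains only common variants.
#'
#' @param cfg a [sim_config()] object.
#' @param seed optional integer seed.
#' @return List with `geno` (a [genotype_data()] with `p + p_kinship` SNPs;
#'   candidates come first), `candidate_idx`, `kinship_idx`, `Q` (admixture
#'   proportions) and `p_anc` (ancestral frequencies).
#' @export
simulate_bnpsd <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  K <- cfg$K
  p_total <- cfg$p + cfg$p_kinship
  Q <- .admixture_q(cfg)

  draw <- function(nsnp) {
    p_anc <- stats::runif(nsnp, 0.01, 0.5)
    Psub <- matrix(0, K, nsnp)
    for (u in seq_len(K)) {
      fu <- cfg$F[u]
      Psub[u, ] <- stats::rbeta(nsnp, p_anc * (1 - fu) / fu,
                                (1 - p_anc) * (1 - fu) / fu)
    }
    pi_ij <- Q %*% Psub
    pi_ij[pi_ij < 0] <- 0
    pi_ij[pi_ij > 1] <- 1
    counts <- matrix(stats::rbinom(n * nsnp, 2L, pi_ij), n, nsnp)
    list(counts = counts, p_anc = p_anc)
  }

  counts <- matrix(0L, n, p_total)
  p_anc <- numeric(p_total)
  chunk <- 2000L
  for (start in seq(1L, p_total, by = chunk)) {
    idx <- start:min(start + chunk - 1L, p_total)
    dr <- draw(length(idx))
    counts[, idx] <- dr$counts
    p_anc[idx] <- dr$p_anc
  }
  # redraw rare/monomorphic SNPs until all pass the common-variant filter
  for (round in seq_len(100)) {
    f <- colMeans(counts) / 2
    maf <- pmin(f, 1 - f)
    bad <- which(maf < 0.01)
    if (!length(bad)) break
    dr <- draw(length(bad))
    counts[, bad] <- dr$counts
    p_anc[bad] <- dr$p_anc
  }
  if (length(bad <- which(pmin(colMeans(counts) / 2,
                               1 - colMeans(counts) / 2) < 0.01))) {
    stop("could not reach MAF >= 0.01 for ", length(bad), " SNP(s)")
  }
  geno <- suppressMessages(genotype_data(counts))
  list(geno = geno, candidate_idx = seq_len(cfg$p),
       kinship_idx = cfg$p + seq_len(cfg$p_kinship), Q = Q, p_anc = p_anc)
}

#' Simulate a binary phenotype with confounded polygenic liability
#'
#' Builds the liability
#' `logit(pi) = logit(pi0) - log(1.3) Sex + log(1.05) Age/10 +
#' sum_{j in S} beta_j gtilde_j + b`
#' with causal effects `beta_j ~ N(0, h_g2 sigma2 / |S|)` acting on
#' standardized genotypes and a polygenic effect `b = U delta`,
#' `delta ~ N(0, h_b2 sigma2 D)`, where `(U, D)` is the eigendecomposition of
#' the kinship-panel GRM, so the unmeasured confounder is correlated with the
#' population structure. The liability scale is anchored by
#' `sigma2 = (pi^2/3) / (1 - h_g2 - h_b2)`: the logistic residual variance
#' `pi^2/3` is the non-genetic share. Age is `N(50, 5^2)` and sex is
#' `Bernoulli(0.5)`.
#'
#' @param g_candidates [genotype_data()] restricted to the candidate SNPs.
#' @param km_true [eigendecompose_kinship()] of the true kinship-panel GRM
#'   (with `tau = 1`, so its eigenvalues are those of the GRM itself).
#' @param cfg a [sim_config()] object.
#' @param seed optional integer seed.
#' @return List of class `SimReplicate`: `y`, `X` (intercept, sex, age),
#'   `age`, `sex`, `causal_set`, `beta_true` (length `p`, zero off the causal
#'   set), `b_true`, `delta`, `sigma2`, and `var_audit` (realized variances
#'   of the liability components).
#' @export
simulate_phenotype <- function(g_candidates, km_true, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g_candidates$counts)
  p <- ncol(g_candidates$counts)
  n_causal <- max(1L, round(p * cfg$c))
  sigma2 <- (pi^2 / 3) / (1 - cfg$h_g2 - cfg$h_b2)

  causal_set <- sort(sample.int(p, n_causal))
  beta_true <- numeric(p)
  beta_true[causal_set] <- stats::rnorm(n_causal,
                                        sd = sqrt(cfg$h_g2 * sigma2 /
                                                    n_causal))
  gs <- standardize_genotypes(
    g_candidates$counts[, causal_set, drop = FALSE],
    maf = g_candidates$maf[causal_set]
  )
  fixed_gen <- drop(gs %*% beta_true[causal_set])

  D <- km_true$eigvals
  delta <- stats::rnorm(length(D), sd = sqrt(cfg$h_b2 * sigma2 * D))
  b <- drop(km_true$U %*% delta)

  age <- stats::rnorm(n, 50, 5)
  sex <- stats::rbinom(n, 1L, 0.5)
  eta <- stats::qlogis(cfg$pi0) - log(1.3) * sex + log(1.05) * age / 10 +
    fixed_gen + b
  y <- stats::rbinom(n, 1L, .expit(eta))

  X <- cbind(`(Intercept)` = 1, sex = sex, age = age)
  structure(
    list(y = y, X = X, age = age, sex = sex, causal_set = causal_set,
         beta_true = beta_true, b_true = b, delta = delta, sigma2 = sigma2,
         var_audit = c(var_fixed_genetic = stats::var(fixed_gen),
                       var_polygenic = stats::var(b),
                       sigma2 = sigma2)),
    class = "SimReplicate"
  )
}

#' Score estimated SNP effects and predictions against simulation truth
#'
#' @param beta_hat length-`p` estimated SNP coefficients.
#' @param truth a [simulate_phenotype()] object (`beta_true`, `causal_set`).
#' @param preds optional held-out risk scores.
#' @param labels optional held-out binary labels (required with `preds`).
#' @return Named numeric vector with `tpr`, `rmse`, `precision` (`NA` when no
#'   SNP is selected) and `auc` (`NA` without predictions).
#' @export
score_replicate <- function(beta_hat, truth, preds = NULL, labels = NULL) {
  p <- length(truth$beta_true)
  if (length(beta_hat) != p) stop("beta_hat must have length p")
  if (!length(truth$causal_set)) stop("empty causal set; TPR undefined")
  sel <- which(beta_hat != 0)
  tp <- length(intersect(sel, truth$causal_set))
  tpr <- tp / length(truth$causal_set)
  rmse <- sqrt(sum((beta_hat - truth$beta_true)^2) / p)
  precision <- if (length(sel)) tp / length(sel) else NA_real_
  auc_val <- if (!is.null(preds)) auc(preds, labels) else NA_real_
  c(tpr = tpr, rmse = rmse, precision = precision, auc = auc_val)
}

#' Restrict a genotype container to a subset of samples
#'
#' Allele frequencies are recomputed on the subset (without re-orienting
#' alleles, so variant identity is preserved).
#'
#' @param g a [genotype_data()] object.
#' @param idx sample indices to keep.
#' @return A [genotype_data()] object for the subset.
#' @export
subset_samples <- function(g, idx) {
  out <- g
  out$counts <- g$counts[idx, , drop = FALSE]
  out$samples <- g$samples[idx]
  if (!is.null(g$fam)) out$fam <- g$fam[idx, , drop = FALSE]
  out$maf <- colMeans(out$counts, na.rm = TRUE) / 2
  out
}

# Fit one method on a train/test split of a simulated replicate and return
# scores at a fixed active-set size. Internal workhorse shared by
# run_scenario1() and the acceptance checks.
# method: "pglmm" (GRM random effect), "pc_lasso" (top n_pcs unpenalized
# PCs), "lasso" (no adjustment).
.fit_one_method <- function(method, sim, geno, train, test, n_active_target,
                            n_pcs = 10L, nlambda = 100L,
                            lambda.min.ratio = 0.01) {
  g_all <- geno$geno
  g_train <- subset_samples(g_all, train)
  g_test <- subset_samples(g_all, test)
  Xtr <- sim$X[train, , drop = FALSE]
  ytr <- sim$y[train]
  Xte <- sim$X[test, , drop = FALSE]
  yte <- sim$y[test]

  V <- estimate_grm(g_train, snp_subset = geno$kinship_idx)
  V12 <- cross_grm(g_test, g_train, attr(V, "snps_used"), attr(V, "maf"))

  cand <- geno$candidate_idx
  Gtr <- standardize_genotypes(g_train$counts[, cand, drop = FALSE],
                               maf = g_train$maf[cand])
  Gte <- standardize_genotypes(g_test$counts[, cand, drop = FALSE],
                               maf = g_train$maf[cand])

  if (method == "pglmm") {
    null <- fit_null_pglmm(Xtr, ytr, V)
    km <- eigendecompose_kinship(V, null$tau)
    path <- pglmm_path(null, km, Gtr, nlambda = nlambda,
                       lambda.min.ratio = lambda.min.ratio,
                       nactive_max = n_active_target + 10L)
    k <- which.min(abs(path$n_active - n_active_target))
    probs <- predict_mixed(path, null, km, cbind(Xte, Gte), V12,
                           which_lambda = k)
    beta_snp <- path$coef[-seq_len(path$m), k]
  } else {
    if (method == "pc_lasso") {
      eigV <- eigendecompose_kinship(V, 1)
      Ur <- eigV$U[, seq_len(n_pcs), drop = FALSE]
      Xtr_m <- cbind(Xtr, Ur)
      Xte_m <- cbind(Xte, V12 %*% Ur) # projected component scores
    } else {
      Xtr_m <- Xtr
      Xte_m <- Xte
    }
    null <- .null_fixed_tau(Xtr_m, ytr)
    km0 <- .km_zero(length(ytr))
    path <- pglmm_path(null, km0, Gtr, nlambda = nlambda,
                       lambda.min.ratio = lambda.min.ratio,
                       nactive_max = n_active_target + 10L)
    k <- which.min(abs(path$n_active - n_active_target))
    eta_te <- drop(cbind(Xte_m, Gte) %*% path$coef[, k])
    probs <- .expit(eta_te)
    beta_snp <- path$coef[-seq_len(path$m), k]
  }
  sc <- score_replicate(beta_snp, sim, preds = as.numeric(probs),
                        labels = yte)
  c(sc, n_active = path$n_active[k])
}

# minimal null-fit object with tau fixed at zero (plain logistic fit);
# used for the unpenalized-PC and unadjusted lasso baselines.
.null_fixed_tau <- function(X, y) {
  glm0 <- stats::glm.fit(X, y, family = stats::binomial())
  alpha <- glm0$coefficients
  eta <- drop(X %*% alpha)
  wu <- working_update(y, eta)
  structure(
    list(alpha = alpha, tau = 0, phi = 1, b = numeric(length(y)), eta = eta,
         mu = wu$mu, W = wu$W, Ytilde = wu$Ytilde, converged = TRUE,
         n_iter = 0L, X = as.matrix(X), y = as.numeric(y), floor_tau = 0),
    class = "NullFit"
  )
}

# kinship model for tau = 0: the rotation is the identity.
.km_zero <- function(n) {
  structure(
    list(Vs = list(matrix(0, n, n)), tau = 0, U = diag(n),
         eigvals = rep(0, n), Lambda = rep(0, n)),
    class = "KinshipModel"
  )
}

#' Run the structured-population variable-selection experiment
#'
#' For each replicate: simulate genotypes and phenotype, split 80/20 into
#' training and test sets, fit each method's lasso path on the training set,
#' take the path point whose active set is closest to `n_active_target`, and
#' score true positive rate, coefficient RMSE, selection precision and
#' held-out AUC against the simulation truth.
#'
#' @param cfg a [sim_config()] object.
#' @param n_reps number of replicates.
#' @param methods subset of `c("pglmm", "pc_lasso", "lasso")`.
#' @param n_active_target fixed number of active SNPs at which methods are
#'   compared (default: the number of causal SNPs).
#' @param n_pcs number of unpenalized principal components for the
#'   `pc_lasso` baseline (default 10).
#' @param seed integer seed; replicate `i` uses `seed + i`.
#' @param train_frac training fraction of the random split (default 0.8).
#' @param verbose print per-replicate progress.
#' @return Data frame with one row per method and replicate: `method`,
#'   `rep`, `tpr`, `rmse`, `precision`, `auc`, `n_active`.
#' @export
run_scenario1 <- function(cfg, n_reps = 5L,
                          methods = c("pglmm", "pc_lasso", "lasso"),
                          n_active_target = NULL, n_pcs = 10L, seed = 1L,
                          train_frac = 0.8, verbose = FALSE) {
  methods <- match.arg(methods, c("pglmm", "pc_lasso", "lasso"),
                       several.ok = TRUE)
  if (is.null(n_active_target)) {
    n_active_target <- max(1L, round(cfg$p * cfg$c))
  }
  rows <- list()
  for (i in seq_len(n_reps)) {
    rep_seed <- seed + i
    set.seed(rep_seed)
    geno <- simulate_bnpsd(cfg)
    V_true <- estimate_grm(geno$geno, snp_subset = geno$kinship_idx)
    km_true <- eigendecompose_kinship(V_true, 1)
    g_cand <- geno$geno
    g_cand$counts <- g_cand$counts[, geno$candidate_idx, drop = FALSE]
    g_cand$maf <- g_cand$maf[geno$candidate_idx]
    g_cand$variants <- g_cand$variants[geno$candidate_idx, , drop = FALSE]
    sim <- simulate_phenotype(g_cand, km_true, cfg)
    n <- cfg$n
    train <- sort(sample.int(n, round(train_frac * n)))
    test <- setdiff(seq_len(n), train)
    # guard: both classes in both sets (resample the split if not)
    tries <- 0
    while ((length(unique(sim$y[train])) < 2 ||
            length(unique(sim$y[test])) < 2) && tries < 20) {
      train <- sort(sample.int(n, round(train_frac * n)))
      test <- setdiff(seq_len(n), train)
      tries <- tries + 1
    }
    for (mth in methods) {
      sc <- .fit_one_method(mth, sim, geno, train, test, n_active_target,
                            n_pcs = n_pcs)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, rep = i, tpr = sc[["tpr"]], rmse = sc[["rmse"]],
        precision = sc[["precision"]], auc = sc[["auc"]],
        n_active = sc[["n_active"]]
      )
      if (verbose) {
        message("rep ", i, " ", mth, ": TPR = ",
                format(sc[["tpr"]], digits = 3), ", AUC = ",
                format(sc[["auc"]], digits = 3))
      }
    }
  }
  do.call(rbind, rows)
}
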