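# Small programmatic fixtures shared across test files.

# unstructured genotype container: independent Binomial(2, maf) dosages
make_geno <- function(n, p, maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rbinom(n * p, 2L, maf), n, p)
  suppressMessages(genotype_data(counts))
}

# a small mixed-model dataset: structured genotypes, one GRM, binary trait
make_mm_data <- function(n = 120, p = 60, p_kin = 300, K = 4, seed = 1,
                         c = 0.05, h_g2 = 0.4, h_b2 = 0.3) {
  cfg <- sim_config(n = n, p = p, p_kinship = p_kin, K = K, c = c,
                    h_g2 = h_g2, h_b2 = h_b2,
                    F = seq(0.05, 0.2, length.out = K))
  set.seed(seed)
  geno <- simulate_bnpsd(cfg)
  V <- estimate_grm(geno$geno, snp_subset = geno$kinship_idx)
  km_true <- eigendecompose_kinship(V, 1)
  g_cand <- geno$geno
  g_cand$counts <- g_cand$counts[, geno$candidate_idx, drop = FALSE]
  g_cand$maf <- g_cand$maf[geno$candidate_idx]
  g_cand$variants <- g_cand$variants[geno$candidate_idx, , drop = FALSE]
  sim <- simulate_phenotype(g_cand, km_true, cfg)
  list(cfg = cfg, geno = geno, g_cand = g_cand, V = V, sim = sim,
       G = standardize_genotypes(g_cand))
}

# surrogate-objective value of the rotated profiled weighted lasso, used to
# check monotonicity of coordinate-descent sweeps
profiled_surrogate <- function(r, w, s, beta, v, lambda) {
  # 0.5 * r' Sigma_b^{-1} r + penalty, with r = ystar - Xstar beta
  0.5 * sum(w * r^2) + lambda * sum(v * abs(beta))
}
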