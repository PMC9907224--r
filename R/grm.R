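#' Estimate the genetic similarity matrix (GRM)
#'
#' Computes `V = G Gt / p_used` from standardized genotypes, optionally
#' restricted to a subset of SNPs and filtered to common variants
#' (MAF >= `maf_min`). For unrelated samples the diagonal averages about 1.
#'
#' @param g a [genotype_data()] object.
#' @param snp_subset integer or logical index of SNPs to use (default: all).
#' @param maf_min minimum minor allele frequency for a SNP to enter the GRM
#'   (default 0.01, the usual common-variant cutoff).
#' @return Symmetric `n x n` numeric matrix with sample ids as dimnames and
#'   attributes `snps_used` (column indices) and `maf` (their frequencies).
#' @export
estimate_grm <- function(g, snp_subset = NULL, maf_min = 0.01) {
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(g$counts))
  if (is.logical(snp_subset)) snp_subset <- which(snp_subset)
  maf <- g$maf[snp_subset]
  keep <- snp_subset[maf >= maf_min & maf <= 1 - maf_min]
  if (!length(keep)) {
    stop("no SNPs with MAF >= ", maf_min, " in the requested subset")
  }
  gs <- standardize_genotypes(
    g$counts[, keep, drop = FALSE],
    maf = g$maf[keep]
  )
  used <- keep[attr(gs, "kept")]
  V <- tcrossprod(gs) / ncol(gs)
  dimnames(V) <- list(g$samples, g$samples)
  attr(V, "snps_used") <- used
  attr(V, "maf") <- g$maf[used]
  V
}

#' Cross genetic similarity between a test and a training set
#'
#' Computes the `n_s x n` similarity `V12 = Gs Gt' / p_used` between test and
#' training individuals, standardizing the test genotypes with the training
#' MAFs so that the block is consistent with the training GRM.
#'
#' @param g_test,g_train [genotype_data()] objects sharing the same variants
#'   (matched by variant id and alleles).
#' @param snps_used SNP indices into the training container, typically the
#'   `snps_used` attribute of the training GRM from [estimate_grm()].
#' @param train_maf training-set frequencies for those SNPs, typically the
#'   `maf` attribute of the training GRM.
#' @return `n_s x n` numeric matrix.
#' @export
cross_grm <- function(g_test, g_train, snps_used, train_maf) {
  vt <- g_train$variants[snps_used, , drop = FALSE]
  vs <- g_test$variants
  idx <- match(vt$id, vs$id)
  if (anyNA(idx)) {
    stop("test set lacks ", sum(is.na(idx)), " training GRM variant(s), e.g. ",
         paste(utils::head(vt$id[is.na(idx)], 3), collapse = ", "))
  }
  same <- vs$allele1[idx] == vt$allele1 & vs$allele2[idx] == vt$allele2
  flipped <- vs$allele1[idx] == vt$allele2 & vs$allele2[idx] == vt$allele1
  if (any(!same & !flipped)) {
    stop("allele mismatch between test and training sets for ",
         sum(!same & !flipped), " variant(s)")
  }
  counts <- g_test$counts[, idx, drop = FALSE]
  if (any(flipped)) counts[, flipped] <- 2L - counts[, flipped]
  gs_test <- standardize_genotypes(counts, maf = train_maf)
  gs_train <- standardize_genotypes(
    g_train$counts[, snps_used, drop = FALSE], maf = train_maf
  )
  V12 <- tcrossprod(gs_test, gs_train) / length(snps_used)
  dimnames(V12) <- list(g_test$samples, g_train$samples)
  V12
}

#' Spectral decomposition of the fitted random-effect covariance
#'
#' Given one or more positive semi-definite similarity matrices `V_s` and
#' nonnegative variance components `tau_s`, eigendecomposes
#' `K = sum_s tau_s V_s` once. The eigenpairs drive both the rotation of the
#' working model during path fitting and the shrinkage factors used in
#' mixed-model prediction.
#'
#' @param Vs a single matrix or a list of symmetric PSD `n x n` matrices.
#' @param tau numeric vector of variance components, one per matrix.
#' @return Object of class `KinshipModel`: list with `Vs` (the input list),
#'   `tau`, `U` (orthonormal eigenvectors of `K`, descending eigenvalue
#'   order), `eigvals` (eigenvalues of `K`, clamped to be nonnegative) and
#'   `Lambda` (eigenvalues of `V_1` alone, same descending order convention).
#' @export
eigendecompose_kinship <- function(Vs, tau) {
  if (is.matrix(Vs)) Vs <- list(Vs)
  if (length(tau) != length(Vs)) stop("need one tau per similarity matrix")
  if (any(tau < 0)) stop("variance components must be nonnegative")
  n <- nrow(Vs[[1]])
  for (s in seq_along(Vs)) {
    V <- Vs[[s]]
    if (!is.matrix(V) || nrow(V) != n || ncol(V) != n) {
      stop("similarity matrix ", s, " is not n x n")
    }
    if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V)))) {
      stop("similarity matrix ", s, " is not symmetric")
    }
  }
  K <- matrix(0, n, n)
  for (s in seq_along(Vs)) K <- K + tau[s] * Vs[[s]]
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  d <- eig$values
  if (length(d) && min(d) < -1e-8 * max(abs(d), 1)) {
    stop("combined covariance has a substantially negative eigenvalue: ",
         format(min(d)))
  }
  d <- pmax(d, 0)
  e1 <- eigen((Vs[[1]] + t(Vs[[1]])) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  structure(
    list(Vs = Vs, tau = tau, U = eig$vectors, eigvals = d,
         Lambda = pmax(e1, 0)),
    class = "KinshipModel"
  )
}

#' @export
print.KinshipModel <- function(x, ...) {
  cat("KinshipModel:", nrow(x$U), "samples,", length(x$Vs),
      "variance component(s); tau =", paste(format(x$tau, digits = 4),
                                            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a kinship matrix as dense CSV with a sample-id header
#'
#' @param V square numeric matrix with sample ids as dimnames.
#' @param path CSV file path.
#' @return `read_kinship_csv` returns the matrix with dimnames restored.
#' @export
write_kinship_csv <- function(V, path) {
  utils::write.csv(as.data.frame(V), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_csv
#' @export
read_kinship_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  V <- as.matrix(tab)
  rownames(V) <- colnames(V)
  V
}
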