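#' AIC along a fitted path
#'
#' `AIC_l = -2 ell_PQL(lambda_l) + 2 df_l`, where `ell_PQL` is the penalized
#' quasi-likelihood (Bernoulli log-likelihood minus the random-effect
#' quadratic form) at the solution and `df_l` counts all nonzero fixed-effect
#' coefficients, unpenalized covariates included.
#'
#' @param path a [pglmm_path()] object.
#' @return Numeric vector of AIC values, one per lambda.
#' @export
aic_path <- function(path) {
  -2 * path$ell_pql + 2 * path$df
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic scaled to `[0, 1]`, with ties counted as half
#' concordant.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels in `{0,1}`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores) # average ranks give half credit to ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Family-aware random partition of samples
#'
#' Splits samples into sets of given fractions while keeping every group of
#' related individuals together: samples whose similarity exceeds
#' `threshold` are connected, and the connected components are assigned
#' atomically. The default threshold `0.0884` is twice the third-degree
#' kinship coefficient on the GRM scale, matching the usual definition of a
#' cohort with first- to third-degree relationships.
#'
#' @param ids character vector of sample ids.
#' @param V `n x n` similarity matrix (e.g. the GRM).
#' @param fractions numeric vector summing to 1 (e.g. `c(0.4, 0.3, 0.3)`).
#' @param seed integer seed driving the component-level randomization.
#' @param threshold relatedness threshold above which two samples must share
#'   a set.
#' @return Integer vector of set labels in `1..length(fractions)`, named by
#'   `ids`.
#' @export
split_families <- function(ids, V, fractions, seed = 1L,
                           threshold = 0.0884) {
  n <- length(ids)
  if (nrow(V) != n) stop("similarity matrix does not match ids")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  # union-find over pairs above the threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  A <- V
  diag(A) <- -Inf
  pairs <- which(A > threshold, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  for (e in seq_len(nrow(pairs))) {
    a <- find(pairs[e, 1])
    b <- find(pairs[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp_ids <- split(seq_len(n), comp)
  sizes <- lengths(comp_ids)
  targets <- fractions * n
  if (max(sizes) > max(targets) * 1.05 + 1) {
    stop("a related component of size ", max(sizes), " exceeds the largest ",
         "set target (", round(max(targets)), "); raise the threshold or ",
         "merge sets")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  ord <- sample(length(comp_ids))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  assign_set <- integer(n)
  filled <- numeric(length(fractions))
  for (ci in ord) {
    # put the component where the relative deficit is largest
    deficit <- (targets - filled) / targets
    k <- which.max(deficit)
    assign_set[comp_ids[[ci]]] <- k
    filled[k] <- filled[k] + sizes[ci]
  }
  names(assign_set) <- ids
  assign_set
}

#' Select the penalty level by AIC or validation AUC
#'
#' @param path a [pglmm_path()] object fitted on training data.
#' @param method `"aic"` (minimize AIC on the training fit) or `"cv"`
#'   (maximize AUC of mixed-model predictions on a held-out validation set).
#' @param null,km training null fit and kinship model (required for
#'   `method = "cv"`).
#' @param Xs_valid,V12_valid,y_valid validation design, cross-GRM and labels
#'   (required for `method = "cv"`).
#' @return Object of class `SelectionResult`: `criterion`, `best_lambda`,
#'   `best_index`, `scores` (per-lambda criterion values), `model_size`
#'   (active SNPs at the optimum), `coef` (coefficients at the optimum).
#'   Ties are broken toward the larger penalty (sparser model).
#' @export
select_lambda <- function(path, method = c("aic", "cv"), null = NULL,
                          km = NULL, Xs_valid = NULL, V12_valid = NULL,
                          y_valid = NULL) {
  method <- match.arg(method)
  if (method == "aic") {
    scores <- aic_path(path)
    best <- which.min(scores) # which.min takes the first (largest lambda)
    criterion <- "aic"
  } else {
    if (is.null(null) || is.null(km) || is.null(Xs_valid) ||
        is.null(V12_valid) || is.null(y_valid)) {
      stop("cv selection needs null, km, Xs_valid, V12_valid and y_valid")
    }
    if (length(unique(y_valid)) < 2L) {
      stop("validation labels contain a single class")
    }
    probs <- predict_mixed(path, null, km, Xs_valid, V12_valid)
    scores <- apply(probs, 2, auc, labels = y_valid)
    best <- which.max(scores)
    criterion <- "cv_auc"
  }
  structure(
    list(criterion = criterion, best_lambda = path$lambda[best],
         best_index = best, scores = scores,
         model_size = path$n_active[best], coef = path$coef[, best]),
    class = "SelectionResult"
  )
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("Model selection by", x$criterion, "\n")
  cat("  best lambda:", format(x$best_lambda, digits = 4), "(index",
      x$best_index, "),", x$model_size, "active SNPs\n")
  invisible(x)
}
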