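# Regularized partial-correlation network estimation: Spearman correlation
# input, positive-semidefinite repair, graphical lasso over a log-spaced
# penalty path, and extended-BIC (gamma = 0.5) model selection.

#' Spearman correlation matrix of the item table
#'
#' Pairwise Spearman correlations (average ranks for ties), chosen over
#' polychoric correlations because item scores are ordinal, skewed, and
#' produce low-frequency cross tables that bias polychoric estimates.
#'
#' @param table Item-response table (numeric columns; no missing values).
#' @param items Item column names to use.
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `n` (number of rows used).
#' @export
spearman_matrix <- function(table,
                            items = intersect(default_item_names(),
                                              names(table))) {
  x <- as.matrix(table[items])
  if (nrow(x) < 3) stop("need at least 3 rows for a correlation matrix")
  if (anyNA(x)) stop("missing values present; filter to complete cases first")
  const <- items[apply(x, 2, function(v) length(unique(v)) == 1)]
  if (length(const))
    stop("correlation undefined for constant item(s): ",
         paste(const, collapse = ", "))
  S <- cor(x, method = "spearman")
  diag(S) <- 1
  attr(S, "n") <- nrow(x)
  S
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Spearman matrices of ordinal data need not be PSD, but the graphical
#' lasso requires it. If the minimum eigenvalue is already nonnegative the
#' input is returned unchanged; otherwise eigenvalues are clipped at
#' `eig_floor`, the matrix reconstructed, and rescaled to unit diagonal.
#'
#' @param corr Symmetric matrix with unit diagonal.
#' @param eig_floor Eigenvalue clip level (default 1e-4).
#' @return A PSD correlation matrix (attributes of `corr` preserved).
#' @export
repair_psd <- function(corr, eig_floor = 1e-4) {
  e <- eigen(corr, symmetric = TRUE)
  if (min(e$values) >= 0) return(corr)
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(corr)
  attr(R, "n") <- attr(corr, "n")
  R
}

#' Log-spaced penalty path for the graphical lasso
#'
#' Runs from `lambda_max` (the largest absolute off-diagonal correlation,
#' at which the estimated network is empty) down to
#' `lambda_max * min_ratio`, strictly decreasing on a log scale.
#'
#' @param corr Correlation matrix.
#' @param n_points Number of path points (default 100).
#' @param min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(corr, n_points = 100, min_ratio = 0.01) {
  stopifnot(n_points >= 2, min_ratio > 0, min_ratio < 1)
  off <- abs(corr[upper.tri(corr)])
  lmax <- max(off)
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; degenerate path")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_points))
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det K - trace(S K) - lambda * sum_{i != j} |K_ij|`
#' (diagonal unpenalised) by block coordinate descent over the working
#' covariance, the standard algorithm for sparse Gaussian graphical
#' models.
#'
#' @param corr PSD correlation matrix.
#' @param lam Penalty, `lam >= 0`.
#' @param tol Convergence tolerance on parameter change, relative to the
#'   mean absolute off-diagonal of `corr` (default 1e-6).
#' @param maxit Maximum outer sweeps (default 500).
#' @return The estimated precision matrix `K` (symmetric positive
#'   definite), with attributes `iterations` and `W` (the working
#'   covariance).
#' @export
graphical_lasso <- function(corr, lam, tol = 1e-6, maxit = 500) {
  stopifnot(lam >= 0)
  fit <- glasso_cpp(unclass(corr)[, , drop = FALSE], lam, tol, maxit)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", maxit,
         " sweeps (achieved parameter change ", format(fit$change), ")")
  K <- fit$K
  dimnames(K) <- dimnames(corr)
  attr(K, "iterations") <- fit$iterations
  attr(K, "W") <- fit$W
  K
}

#' Convert a precision matrix to partial-correlation edge weights
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)`, zero diagonal.
#'
#' @param K Positive-definite precision matrix.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
precision_to_weights <- function(K) {
  d <- sqrt(diag(K))
  W <- -unclass(K) / tcrossprod(d)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  attributes(W) <- list(dim = dim(K), dimnames = dimnames(K))
  W
}

#' Extended Bayesian information criterion for a GGM fit
#'
#' `-2 * (n/2) * (log det K - trace(S K)) + E log n + 4 E gamma log p`,
#' where `E` counts off-diagonal pairs with `|K_ij| > zero_tol` and `p` is
#' the matrix dimension. Constant likelihood terms are dropped; only EBIC
#' differences matter for selection.
#'
#' @param K Precision matrix.
#' @param S Correlation matrix the model was fit to.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (default 0.5, favouring sparse,
#'   interpretable networks).
#' @param zero_tol Threshold below which an entry counts as zero.
#' @return EBIC value.
#' @export
ebic <- function(K, S, n, gamma = 0.5, zero_tol = 1e-8) {
  stopifnot(n >= 1)
  p <- nrow(K)
  Koff <- K
  diag(Koff) <- 0
  E <- sum(abs(Koff[upper.tri(Koff)]) > zero_tol)
  loglik <- (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] -
                         sum(S * K))
  -2 * loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate the regularized symptom network
#'
#' Full estimation chain: Spearman correlations, PSD repair, a log-spaced
#' penalty path, a graphical-lasso fit per penalty (warm-started along the
#' path), and EBIC selection with hyperparameter `gamma`. Exact EBIC ties
#' break toward the larger penalty, i.e. the sparser model. Weight entries
#' below `zero_tol` in absolute value are set exactly to zero so the edge
#' count is well defined in floating point.
#'
#' @param table Complete-case item table.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_points,min_ratio Penalty path control, see [lambda_path()].
#' @param communities Optional named community labels; defaults to the
#'   depression/anxiety split inferred from CESD*/GAD* column names.
#' @param items Item columns.
#' @param zero_tol Edge zero threshold (default 1e-8).
#' @param tol,maxit Solver control, see [graphical_lasso()].
#' @return Object of class `symptom_network`: `weights`, `node_names`,
#'   `communities`, `lambda`, `ebic`, `gamma`, `n`, `path` (per-penalty
#'   EBIC and edge counts), `S` (repaired correlation input).
#' @export
select_network <- function(table, gamma = 0.5, n_points = 100,
                           min_ratio = 0.01, communities = NULL,
                           items = intersect(default_item_names(),
                                             names(table)),
                           zero_tol = 1e-8, tol = 1e-6, maxit = 500) {
  n <- nrow(table)
  if (n < 50)
    warning("only ", n, " rows; regularized network estimates will be noisy")
  S <- spearman_matrix(table, items)
  S <- repair_psd(S)
  lams <- lambda_path(S, n_points, min_ratio)
  fit <- glasso_path_cpp(unclass(S)[, , drop = FALSE], lams, tol, maxit)
  if (!all(fit$converged))
    stop("graphical lasso failed to converge at ",
         sum(!fit$converged), " of ", length(lams), " penalties")
  ebics <- vapply(fit$K, ebic, 0, S = S, n = n, gamma = gamma,
                  zero_tol = zero_tol)
  edges <- vapply(fit$K, function(K) {
    sum(abs(K[upper.tri(K)]) > zero_tol)
  }, 0L)
  best <- which.min(ebics)  # first minimum = largest penalty on ties
  K <- fit$K[[best]]
  dimnames(K) <- dimnames(S)
  W <- precision_to_weights(K)
  W[abs(W) < zero_tol] <- 0

  if (is.null(communities)) {
    communities <- stats::setNames(
      ifelse(grepl("^CESD", items), "depression", "anxiety"), items)
  }
  structure(list(weights = W, node_names = items,
                 communities = communities,
                 lambda = lams[best], ebic = ebics[best],
                 gamma = gamma, n = n,
                 path = data.frame(lambda = lams, ebic = ebics,
                                   edges = edges),
                 S = S, K = K),
            class = "symptom_network")
}

#' Count nonzero edges of a network
#'
#' @param net A `symptom_network` or weight matrix.
#' @return Number of unordered node pairs with nonzero weight.
#' @export
edge_count <- function(net) {
  W <- if (is.list(net)) net$weights else net
  sum(W[upper.tri(W)] != 0)
}

#' @export
print.symptom_network <- function(x, ...) {
  p <- length(x$node_names)
  cat("Regularized partial correlation network\n")
  cat("  nodes:", p, " possible edges:", p * (p - 1) / 2,
      " nonzero edges:", edge_count(x), "\n")
  cat("  n =", x$n, " gamma =", x$gamma,
      " selected lambda =", format(x$lambda, digits = 4),
      " EBIC =", format(x$ebic, digits = 6), "\n")
  invisible(x)
}
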