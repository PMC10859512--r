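# Network accuracy and stability: non-parametric bootstrap CIs for edge
# weights, bootstrapped difference tests, case-dropping bootstrap, and the
# correlation-stability (CS) coefficient.  Every replicate re-runs the
# entire estimation chain including penalty selection, so intervals reflect
# model-selection variability.  Per-replicate seeds are derived from the
# master seed by a counter scheme, making results independent of execution
# order.

upper_pairs <- function(nm) {
  p <- length(nm)
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             edge = paste(nm[ut[, 1]], nm[ut[, 2]], sep = "--"))
}

edge_vector <- function(net) {
  W <- if (is.list(net)) net$weights else net
  W[upper.tri(W)]
}

# Percentile interval from bootstrap draws; inverse-ECDF quantiles (type 1)
# so that B = 2 gives the min/max of the two draws.
boot_ci <- function(draws, level) {
  a <- (1 - level) / 2
  quantile(draws, c(a, 1 - a), type = 1, names = FALSE, na.rm = TRUE)
}

#' Non-parametric bootstrap of edge weights
#'
#' Resamples rows with replacement `B` times, re-runs the full network
#' estimation (Spearman, PSD repair, penalty path, EBIC selection) on each
#' replicate, and forms per-edge percentile confidence intervals from the
#' bootstrap draws. Replicates whose estimation fails are skipped and
#' counted; more than 10% failures is an error.
#'
#' @param table Complete-case item table.
#' @param B Number of bootstrap samples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed.
#' @param ... Passed to [select_network()] (e.g. `gamma`, `n_points`).
#' @return Object of class `edge_bootstrap`: `estimate` (named per-edge
#'   point estimates from the full sample), `draws` (B x n_edges matrix),
#'   `lower`, `upper`, `pairs`, `B`, `failures`, `level`, and the
#'   full-sample `network`.
#' @export
edge_bootstrap <- function(table, B = 1000, level = 0.95, seed = 1, ...) {
  stopifnot(B >= 2, level > 0, level < 1)
  full <- select_network(table, ...)
  est <- edge_vector(full)
  pairs <- upper_pairs(full$node_names)
  n <- nrow(table)

  draws <- matrix(NA_real_, B, length(est))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(sub_seed(seed, b, offset = 1),
                     sample.int(n, n, replace = TRUE))
    rep_net <- tryCatch(
      suppressWarnings(select_network(table[idx, , drop = FALSE], ...)),
      error = function(e) NULL)
    if (is.null(rep_net)) failures <- failures + 1L
    else draws[b, ] <- edge_vector(rep_net)
  }
  if (failures > 0.10 * B)
    stop(failures, " of ", B, " bootstrap replicates failed estimation")
  draws <- draws[!is.na(draws[, 1]), , drop = FALSE]
  cis <- apply(draws, 2, boot_ci, level = level)
  structure(list(estimate = stats::setNames(est, pairs$edge),
                 draws = draws, lower = cis[1, ], upper = cis[2, ],
                 pairs = pairs, B = B, failures = failures, level = level,
                 network = full),
            class = "edge_bootstrap")
}

#' Bootstrapped difference test
#'
#' Two statistics differ significantly at level `alpha` if the
#' `(alpha/2, 1 - alpha/2)` percentile interval of their paired
#' per-replicate bootstrap differences excludes zero.
#'
#' @param draws_a,draws_b Equal-length vectors of paired bootstrap draws
#'   (same replicates).
#' @param alpha Significance level (default 0.05).
#' @return Logical flag, with the difference CI attached as attribute
#'   `"ci"`.
#' @export
difference_test <- function(draws_a, draws_b, alpha = 0.05) {
  if (length(draws_a) != length(draws_b))
    stop("paired draws must have equal length")
  ci <- boot_ci(draws_a - draws_b, 1 - alpha)
  sig <- ci[1] > 0 || ci[2] < 0
  attr(sig, "ci") <- ci
  sig
}

#' All-pairs bootstrapped difference tests
#'
#' @param draws B x m matrix of bootstrap draws (columns = statistics).
#' @param alpha Significance level.
#' @param subset Optional column indices to test (e.g. only edges nonzero
#'   in the full-sample network).
#' @return Symmetric logical matrix of significance flags, diagonal FALSE.
#' @export
difference_test_matrix <- function(draws, alpha = 0.05, subset = NULL) {
  if (!is.null(subset)) draws <- draws[, subset, drop = FALSE]
  m <- ncol(draws)
  out <- matrix(FALSE, m, m, dimnames = list(colnames(draws),
                                             colnames(draws)))
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- difference_test(draws[, i], draws[, j], alpha)
      out[i, j] <- out[j, i] <- as.logical(s)
    }
  }
  out
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `q`, draws `B` subsamples of size
#' `ceiling((1 - q) * n)` without replacement, re-estimates the network,
#' and records the Pearson correlation between the subsample and
#' full-sample statistic vectors (EI, BEI, or edge weights). A correlation
#' is recorded as `NA` when the subsample statistic is constant (e.g. an
#' empty network); such replicates count against stability.
#'
#' @param table Complete-case item table.
#' @param statistic One of `"EI"`, `"BEI"`, `"edge"`.
#' @param proportions Increasing drop proportions in (0, 1); default
#'   0.05 to 0.75 in steps of 0.05, capping the CS-coefficient at 0.75.
#' @param B Subsamples per proportion (default 1000).
#' @param seed Master seed.
#' @param ... Passed to [select_network()].
#' @return Object of class `case_drop`: `proportions`, `cors`
#'   (B x length(proportions) matrix), `statistic`, `B`, `n`, `full_stat`.
#' @export
case_dropping <- function(table, statistic = c("EI", "BEI", "edge"),
                          proportions = seq(0.05, 0.75, by = 0.05),
                          B = 1000, seed = 1, ...) {
  statistic <- match.arg(statistic)
  stopifnot(all(proportions > 0), all(proportions < 1),
            !is.unsorted(proportions, strictly = TRUE))
  n <- nrow(table)
  if (ceiling((1 - max(proportions)) * n) < 20)
    stop("largest drop proportion leaves fewer than 20 rows")
  full <- select_network(table, ...)
  stat_of <- function(net) switch(statistic,
    EI = expected_influence(net),
    BEI = bridge_expected_influence(net),
    edge = edge_vector(net))
  full_stat <- stat_of(full)

  cors <- matrix(NA_real_, B, length(proportions))
  for (qi in seq_along(proportions)) {
    m <- ceiling((1 - proportions[qi]) * n)
    for (b in seq_len(B)) {
      idx <- with_seed(sub_seed(seed, b, offset = 100 + qi),
                       sample.int(n, m, replace = FALSE))
      sub_net <- tryCatch(
        suppressWarnings(select_network(table[idx, , drop = FALSE], ...)),
        error = function(e) NULL)
      if (is.null(sub_net)) next
      s <- stat_of(sub_net)
      if (sd(s) == 0 || sd(full_stat) == 0) next
      cors[b, qi] <- cor(full_stat, s)
    }
  }
  colnames(cors) <- paste0("q", proportions)
  structure(list(proportions = proportions, cors = cors,
                 statistic = statistic, B = B, n = n,
                 full_stat = full_stat),
            class = "case_drop")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion at which at least `prob` of the
#' subsample-vs-full correlations stay at or above `cor_threshold`;
#' 0 if no tested proportion qualifies. Values below 0.25 indicate
#' unstable estimates; above 0.5 is ideal.
#'
#' @param result A `case_drop` object.
#' @param cor_threshold Correlation threshold (default 0.7).
#' @param prob Required probability of exceeding the threshold
#'   (default 0.95).
#' @return CS-coefficient (one of the tested proportions, or 0).
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "case_drop") || is.list(result))
  ok <- vapply(seq_along(result$proportions), function(qi) {
    cc <- result$cors[, qi]
    mean(!is.na(cc) & cc >= cor_threshold) >= prob
  }, logical(1))
  if (!any(ok)) return(0)
  max(result$proportions[ok])
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat("Edge-weight bootstrap:", x$B, "samples (",
      x$failures, "failed ),", length(x$estimate), "edges,",
      sprintf("%d%% percentile CIs\n", round(100 * x$level)))
  invisible(x)
}

#' @export
print.case_drop <- function(x, ...) {
  cat("Case-dropping bootstrap of", x$statistic, ":", x$B,
      "subsamples per proportion, n =", x$n, "\n")
  cat("  CS-coefficient:", cs_coefficient(x), "\n")
  invisible(x)
}
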