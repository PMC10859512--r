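# Synthetic ordinal survey data with a known sparse partial-correlation
# structure.  A latent multivariate-normal vector is discretised at
# item-specific thresholds (a Gaussian copula threshold model), which is the
# generative model under which Spearman-based Gaussian graphical model
# estimation is meaningful for 0-3 Likert items.

#' Default marginal calibration targets for the 17 items
#'
#' Per-item target means and standard deviations on the 0-3 scale used to
#' calibrate the default discretisation thresholds. The profile is
#' right-skewed in the way community surveys of older adults typically are:
#' depression items are endorsed far more often (means 0.50-1.45) than
#' anxiety items (means 0.12-0.32).
#'
#' @return A data frame with columns `item`, `mean`, `sd`.
#' @export
default_marginals <- function() {
  data.frame(
    item = default_item_names(),
    mean = c(0.79, 1.02, 0.73, 1.06, 1.29, 0.65, 1.45, 0.64, 0.50, 1.36,
             0.32, 0.23, 0.28, 0.20, 0.16, 0.20, 0.12),
    sd   = c(0.58, 0.70, 0.58, 0.73, 0.88, 0.60, 0.92, 0.65, 0.60, 0.77,
             0.56, 0.51, 0.54, 0.47, 0.42, 0.47, 0.38),
    stringsAsFactors = FALSE
  )
}

#' Calibrate thresholds for one ordinal item
#'
#' Finds three strictly increasing cut points on the latent standard-normal
#' scale such that the implied 0-3 category distribution matches a target
#' mean and standard deviation as closely as possible (least squares on the
#' two moments; the third degree of freedom is resolved by the optimizer's
#' deterministic start at the moment-matched Gaussian discretisation).
#'
#' @param target_mean Target item mean on the 0-3 scale.
#' @param target_sd Target item standard deviation.
#' @return Numeric vector of three increasing cut points.
#' @export
calibrate_thresholds <- function(target_mean, target_sd) {
  stopifnot(target_mean > 0, target_mean < 3, target_sd > 0)
  moments <- function(t) {
    p <- diff(c(0, pnorm(t), 1))
    m <- sum(p * 0:3)
    v <- sum(p * (0:3)^2) - m^2
    c(m, sqrt(max(v, 0)))
  }
  # unconstrained parametrisation keeps cuts strictly increasing
  unpack <- function(th) cumsum(c(th[1], exp(th[2]), exp(th[3])))
  obj <- function(th) {
    mm <- moments(unpack(th))
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  # start: cuts of a normal with the target mean/sd at category midpoints
  start_cuts <- sort((c(0.5, 1.5, 2.5) - target_mean) / target_sd)
  start_cuts <- start_cuts + cumsum(c(0, rep(1e-3, 2)))
  th0 <- c(start_cuts[1], log(diff(start_cuts)))
  fit <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  unpack(fit$par)
}

#' Default threshold set calibrated to the default marginals
#'
#' @param marginals Data frame with `item`, `mean`, `sd` columns
#'   (default [default_marginals()]).
#' @return A matrix with one row per item and three increasing cut points
#'   per row.
#' @export
default_thresholds <- function(marginals = default_marginals()) {
  th <- t(vapply(seq_len(nrow(marginals)), function(i) {
    calibrate_thresholds(marginals$mean[i], marginals$sd[i])
  }, numeric(3)))
  rownames(th) <- marginals$item
  colnames(th) <- c("t1", "t2", "t3")
  th
}

validate_thresholds <- function(thresholds) {
  if (!is.matrix(thresholds) || ncol(thresholds) != 3)
    stop("thresholds must be a matrix with 3 cut points per item")
  bad <- which(apply(thresholds, 1, function(t) any(diff(t) <= 0)))
  if (length(bad))
    stop("thresholds not strictly increasing for item(s): ",
         paste(rownames(thresholds)[bad] %||% bad, collapse = ", "))
  invisible(thresholds)
}

#' Construct a ground-truth partial-correlation network
#'
#' Builds a two-community (depression + anxiety) symmetric partial
#' correlation matrix: within-community edges are sampled at the requested
#' density with weights drawn uniformly from `within_weight_range`;
#' cross-community "bridge" edges are given explicitly. If the implied
#' precision matrix (unit diagonal, off-diagonal `-w_ij`) is not positive
#' definite with minimum eigenvalue at least `eig_floor`, all weights are
#' shrunk uniformly toward zero by the exact factor that restores the floor,
#' preserving the relative edge structure; the factor is stored as
#' `$shrink`.
#'
#' @param n_dep,n_anx Number of depression / anxiety nodes (default 10 + 7).
#' @param within_weight_range Length-2 interval for within-community edge
#'   weights.
#' @param bridge_edges List of `list(a, b, w)` triples naming the
#'   cross-community edges (node names or indices) and their weights.
#'   Defaults to the package's bridge set: one 0.10 edge and five 0.05-0.06
#'   edges linking the anxiety hub GAD1 (and GAD3) to depression items.
#' @param density Fraction of within-community node pairs that receive an
#'   edge, per community.
#' @param seed Integer seed controlling edge placement and weights.
#' @param eig_floor Minimum eigenvalue of the implied precision matrix.
#' @return An object of class `true_network` with elements `weights`
#'   (p x p symmetric, zero diagonal), `communities`, `node_names`,
#'   `shrink`.
#' @export
make_true_network <- function(n_dep = 10, n_anx = 7,
                              within_weight_range = c(0.10, 0.39),
                              bridge_edges = default_bridge_edges(),
                              density = 0.40, seed = 1,
                              eig_floor = 0.05) {
  stopifnot(n_dep >= 1, n_anx >= 1, length(within_weight_range) == 2,
            density >= 0, density <= 1, eig_floor > 0, eig_floor < 1)
  if (any(abs(within_weight_range) >= 1))
    stop("within-community weights must lie in (-1, 1)")
  p <- n_dep + n_anx
  nm <- default_item_names(n_dep, n_anx)
  comm <- default_communities(n_dep, n_anx)
  W <- matrix(0, p, p, dimnames = list(nm, nm))

  with_seed(seed, {
    for (block in list(seq_len(n_dep), n_dep + seq_len(n_anx))) {
      if (length(block) < 2) next
      pairs <- utils::combn(block, 2)
      n_edges <- round(density * ncol(pairs))
      if (n_edges > ncol(pairs))
        stop("requested density not achievable within community")
      if (n_edges > 0) {
        pick <- sample(ncol(pairs), n_edges)
        w <- runif(n_edges, within_weight_range[1], within_weight_range[2])
        for (e in seq_len(n_edges)) {
          i <- pairs[1, pick[e]]; j <- pairs[2, pick[e]]
          W[i, j] <- W[j, i] <- w[e]
        }
      }
    }
  })

  for (be in bridge_edges) {
    a <- be[[1]]; b <- be[[2]]; w <- be[[3]]
    ia <- if (is.character(a)) match(a, nm) else as.integer(a)
    ib <- if (is.character(b)) match(b, nm) else as.integer(b)
    if (is.na(ia) || is.na(ib) || ia < 1 || ib < 1 || ia > p || ib > p)
      stop("bridge edge refers to unknown node: ", a, " -- ", b)
    if (abs(w) >= 1)
      stop("impossible edge weight ", w, " (|w| must be < 1) on edge ",
           nm[ia], " -- ", nm[ib])
    W[ia, ib] <- W[ib, ia] <- w
  }

  shrink <- 1
  if (any(W != 0)) {
    # precision = I - W_off; eigenvalues are 1 - mu_i with mu_i the
    # eigenvalues of W, so the exact shrink factor has closed form
    mu_max <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
    if (1 - mu_max < eig_floor) {
      shrink <- (1 - eig_floor) / mu_max
      W <- W * shrink
    }
  }

  structure(list(weights = W, communities = comm, node_names = nm,
                 shrink = shrink),
            class = "true_network")
}

#' Default cross-community bridge edges
#'
#' A weak bridge set dominated by the anxiety item GAD1
#' (nervousness/anxiety): weight 0.10 to sleep disturbance (CESD10) and
#' 0.05 to four further depression items, plus a 0.06 edge from CESD4
#' (everything an effort) to GAD3 (worrying too much).
#'
#' @return List of `list(a, b, w)` triples.
#' @export
default_bridge_edges <- function() {
  list(list("GAD1", "CESD10", 0.10),
       list("GAD1", "CESD3", 0.05),
       list("GAD1", "CESD4", 0.05),
       list("GAD1", "CESD5", 0.05),
       list("GAD1", "CESD6", 0.05),
       list("CESD4", "GAD3", 0.06))
}

implied_precision <- function(net) {
  P <- -net$weights
  diag(P) <- 1
  P
}

#' Latent correlation matrix implied by a true network
#'
#' Inverts the implied precision matrix (unit diagonal, off-diagonal
#' `-w_ij`) and rescales to unit diagonal. Converting the result back
#' through precision -> partial correlations recovers the network weights
#' exactly (diagonal rescaling leaves partial correlations invariant).
#'
#' @param net A `true_network`.
#' @return A p x p correlation matrix.
#' @export
true_covariance <- function(net) {
  P <- implied_precision(net)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied precision matrix is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  S <- solve(P)
  R <- stats::cov2cor(S)
  dimnames(R) <- dimnames(net$weights)
  R
}

#' Sample ordinal item responses from a latent Gaussian model
#'
#' Draws `n` latent multivariate-normal vectors with correlation `cov` and
#' discretises each coordinate at its item's thresholds into categories
#' 0-3.
#'
#' @param cov Latent correlation matrix (p x p).
#' @param thresholds p x 3 matrix of increasing cut points
#'   (default [default_thresholds()]).
#' @param n Number of respondents.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Data frame with `participant_id` and one integer column per item.
#' @export
sample_ordinal <- function(cov, thresholds = default_thresholds(), n,
                           seed = 1) {
  stopifnot(n >= 1)
  p <- nrow(cov)
  if (nrow(thresholds) != p)
    stop("dimension mismatch: cov has ", p, " items but thresholds has ",
         nrow(thresholds))
  validate_thresholds(thresholds)
  L <- chol(cov)
  Z <- with_seed(seed, matrix(rnorm(n * p), n, p)) %*% L
  items <- vapply(seq_len(p), function(j) {
    findInterval(Z[, j], thresholds[j, ])
  }, integer(n))
  if (n == 1) items <- matrix(items, nrow = 1)
  colnames(items) <- colnames(cov) %||% rownames(thresholds) %||%
    paste0("item", seq_len(p))
  out <- data.frame(participant_id = seq_len(n), items,
                    check.names = FALSE)
  out
}

#' Inject survey-style missingness completely at random
#'
#' Replaces a fraction of item cells with missing-code tokens, each missing
#' cell receiving one of the codes uniformly at random. Cells are
#' independent Bernoulli(`rate`), so the number of missing cells is binomial.
#'
#' @param table A survey table whose item columns are named in `items`.
#' @param rate Missingness probability per cell in `[0, 1)`.
#' @param seed Integer seed.
#' @param items Character vector of item column names (default: all
#'   CESD/GAD columns present).
#' @param codes Missing-code tokens to use.
#' @return The table with affected item columns converted to character and
#'   missing cells holding code tokens. `rate = 0` returns the input
#'   unchanged.
#' @export
inject_missing <- function(table, rate, seed = 1,
                           items = intersect(default_item_names(),
                                             names(table)),
                           codes = default_missing_codes()) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  with_seed(seed, {
    for (col in items) {
      hit <- runif(nrow(table)) < rate
      if (any(hit)) {
        v <- as.character(table[[col]])
        v[hit] <- sample(codes, sum(hit), replace = TRUE)
        table[[col]] <- v
      }
    }
  })
  table
}

#' @export
print.true_network <- function(x, ...) {
  p <- length(x$node_names)
  ec <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("True symptom network:", p, "nodes,", ec, "edges",
      sprintf("(communities: %s)",
              paste(names(table(x$communities)), collapse = " + ")), "\n")
  if (x$shrink < 1)
    cat("  weights uniformly shrunk by factor",
        format(x$shrink, digits = 4),
        "to keep the implied precision positive definite\n")
  invisible(x)
}

#' Write / read a survey table as CSV
#'
#' Missing codes are written verbatim as string tokens; everything else is
#' plain CSV with a header row.
#'
#' @param table Survey table.
#' @param path File path.
#' @return `read_survey_csv` returns the table with item columns left as
#'   read (integer when fully observed, character when codes are present).
#' @export
write_survey_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a true network to edge-list + node CSVs
#'
#' @param net A `true_network`.
#' @param edge_path,node_path Output CSV paths.
#' @export
write_network_csv <- function(net, edge_path, node_path) {
  ut <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(node_a = net$node_names[ut[, 1]],
                      node_b = net$node_names[ut[, 2]],
                      weight = net$weights[ut])
  nodes <- data.frame(name = net$node_names,
                      community = unname(net$communities))
  write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(edge_path, node_path) {
  edges <- read.csv(edge_path, stringsAsFactors = FALSE)
  nodes <- read.csv(node_path, stringsAsFactors = FALSE)
  p <- nrow(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes$name, nodes$name))
  for (i in seq_len(nrow(edges))) {
    W[edges$node_a[i], edges$node_b[i]] <- edges$weight[i]
    W[edges$node_b[i], edges$node_a[i]] <- edges$weight[i]
  }
  structure(list(weights = W,
                 communities = stats::setNames(nodes$community, nodes$name),
                 node_names = nodes$name, shrink = 1),
            class = "true_network")
}
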