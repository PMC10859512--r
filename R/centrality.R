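# Node-level influence statistics on the estimated network.  Expected
# influence keeps edge signs (the appropriate choice when networks can
# contain negative edges); bridge expected influence restricts the sum to
# cross-community edges.

as_weight_matrix <- function(net) {
  W <- if (is.list(net)) net$weights else net
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10) stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  W
}

#' Expected influence (EI)
#'
#' The signed sum of the weights of all edges attached to each node
#' (one-step EI).
#'
#' @param net A `symptom_network` or symmetric weight matrix with zero
#'   diagonal.
#' @return Named numeric vector of per-node EI.
#' @export
expected_influence <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(W)
}

#' Node strength
#'
#' The sum of absolute edge weights per node.
#'
#' @inheritParams expected_influence
#' @return Named numeric vector of per-node strength.
#' @export
node_strength <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(abs(W))
}

#' Bridge expected influence (BEI)
#'
#' The signed sum of each node's edge weights to nodes in the other
#' community; quantifies its potential for cross-disorder contagion.
#'
#' @inheritParams expected_influence
#' @param communities Named per-node community labels; defaults to the
#'   labels stored in `net`.
#' @return Named numeric vector of per-node BEI.
#' @export
bridge_expected_influence <- function(net, communities = NULL) {
  W <- as_weight_matrix(net)
  if (is.null(communities) && is.list(net)) communities <- net$communities
  nm <- rownames(W) %||% seq_len(nrow(W))
  comm <- communities[nm]
  if (length(comm) != nrow(W) || any(is.na(comm)))
    stop("every node needs a community label; missing for: ",
         paste(nm[is.na(comm)], collapse = ", "))
  cross <- outer(comm, comm, FUN = "!=")
  rowSums(W * cross)
}

#' z-standardize a centrality vector
#'
#' @param values Per-node statistic (length >= 2, nonzero spread).
#' @return Vector with mean 0 and SD 1 (n - 1 divisor).
#' @export
standardize_scores <- function(values) {
  stopifnot(length(values) >= 2)
  s <- sd(values)
  if (s == 0) stop("zero spread: z-scores undefined")
  (values - mean(values)) / s
}

#' Centrality table for a network
#'
#' Raw EI, BEI and strength per node (the primary outputs), plus their
#' z-standardized variants for plotting. A statistic with zero spread
#' (e.g. BEI in a network without cross-community edges) gets `NA`
#' z-scores rather than an error.
#'
#' @param net A `symptom_network` (or weight matrix plus `communities`).
#' @param communities Named community labels if `net` is a bare matrix.
#' @return Data frame with columns `name`, `community`, `EI`, `BEI`,
#'   `strength`, `zEI`, `zBEI`, `zstrength` in fixed order.
#' @export
centrality_table <- function(net, communities = NULL) {
  W <- as_weight_matrix(net)
  if (is.null(communities) && is.list(net)) communities <- net$communities
  ei <- expected_influence(W)
  bei <- bridge_expected_influence(W, communities)
  st <- node_strength(W)
  nm <- rownames(W)
  z <- function(x) if (sd(x) == 0) rep(NA_real_, length(x))
       else unname(standardize_scores(x))
  data.frame(name = nm, community = unname(communities[nm]),
             EI = unname(ei), BEI = unname(bei), strength = unname(st),
             zEI = z(ei), zBEI = z(bei), zstrength = z(st),
             row.names = NULL)
}
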