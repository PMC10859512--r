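# Shared fixtures, built in code at test time.

# A sparse 17-node two-community network with chain backbones: strong
# within-community edges and the default weak bridge set.  `within` is
# recycled along the 15 chain edges; the default spans the strong-edge
# range 0.25-0.39.  Row sums stay below 1, so the implied precision is
# diagonally dominant and no shrinkage is applied.
chain_network <- function(within = c(0.25, 0.3, 0.35, 0.39)) {
  nm <- c(sprintf("CESD%d", 1:10), sprintf("GAD%d", 1:7))
  W <- matrix(0, 17, 17, dimnames = list(nm, nm))
  within <- rep_len(within, 15)
  for (i in 1:9) W[i, i + 1] <- W[i + 1, i] <- within[i]
  for (i in 11:16) W[i, i + 1] <- W[i + 1, i] <- within[i - 1]
  for (be in default_bridge_edges()) {
    W[be[[1]], be[[2]]] <- W[be[[2]], be[[1]]] <- be[[3]]
  }
  structure(list(weights = W,
                 communities = setNames(rep(c("depression", "anxiety"),
                                            c(10, 7)), nm),
                 node_names = nm, shrink = 1),
            class = "true_network")
}

# Small complete-case item table simulated from a true network.
simulate_items <- function(net, n, seed = 1, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- cached_thresholds()
  tab <- sample_ordinal(true_covariance(net), thresholds, n, seed = seed)
  tab[, -1]
}

# default_thresholds() runs 17 small optimizations; cache across tests.
cached_thresholds <- local({
  th <- NULL
  function() {
    if (is.null(th)) th <<- default_thresholds()
    th
  }
})

# Raw survey rows for filter tests: explicit ages, flags and item values.
make_raw_row <- function(age, dm = 1, items = rep(1, 17), id = 1) {
  nm <- c(sprintf("CESD%d", 1:10), sprintf("GAD%d", 1:7))
  out <- data.frame(participant_id = id, age = age, dm_diagnosed = dm)
  for (k in seq_along(nm)) out[[nm[k]]] <- items[k]
  out
}
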