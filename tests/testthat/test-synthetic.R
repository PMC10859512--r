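test_that("empty and two-node networks give the exact closed-form precision", {
  empty <- make_true_network(within_weight_range = c(0, 0),
                             bridge_edges = list(), density = 0, seed = 1)
  expect_equal(empty$weights, matrix(0, 17, 17,
                                     dimnames = dimnames(empty$weights)))
  expect_equal(unname(true_covariance(empty)), diag(17))

  two <- make_true_network(n_dep = 1, n_anx = 1,
                           within_weight_range = c(0, 0),
                           bridge_edges = list(list("CESD1", "GAD1", 0.5)),
                           density = 0, seed = 1)
  P <- -two$weights; diag(P) <- 1
  expect_equal(unname(P), matrix(c(1, -0.5, -0.5, 1), 2))
  expect_equal(sort(eigen(P, symmetric = TRUE)$values), c(0.5, 1.5))
  expect_equal(unname(true_covariance(two)[1, 2]), 0.5)
})

test_that("impossible edge weights are rejected with the offending edge named", {
  expect_error(
    make_true_network(n_dep = 1, n_anx = 1,
                      within_weight_range = c(0, 0),
                      bridge_edges = list(list("CESD1", "GAD1", 1.0)),
                      density = 0),
    "CESD1 -- GAD1")
  expect_error(make_true_network(within_weight_range = c(0.99, 1.0)),
               "\\(-1, 1\\)")
})

test_that("default network has a positive-definite implied precision", {
  net <- make_true_network(seed = 1)
  P <- -net$weights; diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # shrinkage honours the configured eigenvalue floor
  expect_gte(min(ev), 0.05 - 1e-10)
  expect_lte(net$shrink, 1)
})

test_that("3-node chain marginally correlates nodes with zero partial correlation", {
  net <- make_true_network(n_dep = 2, n_anx = 1,
                           within_weight_range = c(0, 0), density = 0,
                           bridge_edges = list(list("CESD2", "GAD1", 0.3)),
                           seed = 1)
  net$weights["CESD1", "CESD2"] <- net$weights["CESD2", "CESD1"] <- 0.3
  R <- true_covariance(net)
  # independent oracle: adjugate of the 3x3 precision by hand
  P <- matrix(c(1, -0.3, 0, -0.3, 1, -0.3, 0, -0.3, 1), 3)
  adj13 <- P[2, 1] * P[3, 2] - P[2, 2] * P[3, 1]  # cofactor C31
  expect_gt(adj13, 0)
  expect_gt(R["CESD1", "GAD1"], 0)
  expect_equal(unname(R["CESD1", "GAD1"]),
               adj13 / sqrt((P[2, 2] * P[3, 3] - P[2, 3]^2) *
                            (P[1, 1] * P[2, 2] - P[1, 2]^2)),
               tolerance = 1e-12)
  K <- solve(R)
  expect_equal(-K[1, 3] / sqrt(K[1, 1] * K[3, 3]), 0, tolerance = 1e-10)
})

test_that("covariance -> precision -> partial correlation round trip is exact", {
  for (seed in 1:5) {
    net <- make_true_network(seed = seed, density = 0.3)
    R <- true_covariance(net)
    K <- solve(R)
    W <- -K / tcrossprod(sqrt(diag(K)))
    diag(W) <- 0
    expect_equal(W, net$weights, tolerance = 1e-10)
  }
})

test_that("ordinal sampling is deterministic and respects thresholds", {
  net <- chain_network()
  R <- true_covariance(net)
  th <- cached_thresholds()
  t1 <- sample_ordinal(R, th, n = 200, seed = 42)
  t2 <- sample_ordinal(R, th, n = 200, seed = 42)
  expect_identical(t1, t2)
  t3 <- sample_ordinal(R, th, n = 200, seed = 43)
  expect_false(identical(t1, t3))

  # all cut points far above the latent range force category 0 everywhere
  high <- matrix(rep(c(8, 9, 10), each = 17), 17)
  rownames(high) <- rownames(th)
  all0 <- sample_ordinal(R, high, n = 50, seed = 1)
  expect_true(all(as.matrix(all0[, -1]) == 0))

  expect_error(sample_ordinal(R[1:5, 1:5], th, n = 10, seed = 1),
               "dimension mismatch")
})

test_that("sample Spearman correlations track the latent structure", {
  th <- cached_thresholds()
  ind <- sample_ordinal(diag(17), th, n = 5000, seed = 11)
  S <- spearman_matrix(ind, items = names(ind)[-1])
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)

  R <- diag(17)
  R[1, 2] <- R[2, 1] <- 0.9
  dimnames(R) <- list(rownames(th), rownames(th))
  # symmetric mid-scale thresholds keep discretisation loss small
  sym <- matrix(rep(c(-1, 0, 1), each = 17), 17,
                dimnames = list(rownames(th), NULL))
  dep <- sample_ordinal(R, sym, n = 5000, seed = 12)
  r12 <- cor(dep$CESD1, dep$CESD2, method = "spearman")
  expect_gt(r12, 0.7)
})

test_that("calibrated thresholds reproduce the target marginals", {
  targets <- default_marginals()
  th <- cached_thresholds()
  # population check: threshold-implied means hit the targets almost exactly
  pop_means <- apply(th, 1, function(t) sum(diff(c(0, pnorm(t), 1)) * 0:3))
  expect_equal(unname(pop_means), targets$mean, tolerance = 0.005)
  # Monte-Carlo check at n = 10,000
  big <- sample_ordinal(diag(17), th, n = 10000, seed = 5)
  means <- colMeans(big[, -1])
  expect_true(all(abs(means - targets$mean) < 0.05))
  # right-skew: every anxiety item rarer than every depression item
  expect_lt(max(means[11:17]), min(means[1:10]) + 1e-9)
})

test_that("missingness injection is MCAR at the requested rate", {
  net <- chain_network()
  tab <- sample_ordinal(true_covariance(net), cached_thresholds(),
                        n = 1000, seed = 2)
  expect_identical(inject_missing(tab, 0, seed = 1), tab)

  miss <- inject_missing(tab, 0.1, seed = 9)
  cells <- as.matrix(miss[, -1])
  n_missing <- sum(cells %in% default_missing_codes())
  # binomial(17000, 0.1): +/- 4.5 SD band
  expect_lt(abs(n_missing - 1700), 4.5 * sqrt(17000 * 0.1 * 0.9))
  expect_identical(inject_missing(tab, 0.1, seed = 9), miss)

  # non-missing cells still valid categories
  kept <- cells[!(cells %in% default_missing_codes())]
  expect_true(all(kept %in% as.character(0:3)))
})

test_that("survey and network CSV round trips preserve content", {
  dir <- withr::local_tempdir()
  net <- chain_network()
  ep <- file.path(dir, "edges.csv"); np <- file.path(dir, "nodes.csv")
  write_network_csv(net, ep, np)
  back <- read_network_csv(ep, np)
  expect_equal(back$weights, net$weights)
  expect_equal(back$communities, net$communities)

  tab <- inject_missing(sample_ordinal(true_covariance(net),
                                       cached_thresholds(), 50, seed = 3),
                        0.2, seed = 4)
  sp <- file.path(dir, "survey.csv")
  write_survey_csv(tab, sp)
  rt <- read_survey_csv(sp)
  expect_equal(names(rt), names(tab))
  expect_equal(nrow(rt), 50)
  mixed <- vapply(tab[-1], is.character, TRUE)
  expect_true(any(mixed))
  expect_equal(as.character(unlist(rt[-1][mixed])),
               as.character(unlist(tab[-1][mixed])))
})
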