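test_that("Spearman matrix uses average ranks and flags constant items", {
  tab <- data.frame(CESD1 = c(0, 1, 2, 3), CESD2 = c(0, 1, 2, 3),
                    CESD3 = c(3, 2, 1, 0))
  S <- spearman_matrix(tab, items = names(tab))
  expect_equal(S["CESD1", "CESD2"], 1)
  expect_equal(S["CESD1", "CESD3"], -1)
  expect_equal(diag(S), setNames(rep(1, 3), names(tab)))

  # ties: Pearson correlation of the average-rank vectors by hand
  t2 <- data.frame(CESD1 = c(0, 0, 1), CESD2 = c(0, 1, 1))
  S2 <- spearman_matrix(t2, items = names(t2))
  expect_equal(S2["CESD1", "CESD2"],
               cor(c(1.5, 1.5, 3), c(1, 2.5, 2.5)))
  expect_equal(unname(S2["CESD1", "CESD2"]), 0.5)

  t3 <- data.frame(CESD1 = c(0, 1, 2), CESD2 = c(2, 2, 2))
  expect_error(spearman_matrix(t3, items = names(t3)), "CESD2")
})

test_that("PSD repair leaves valid matrices alone and fixes indefinite ones", {
  expect_identical(repair_psd(diag(4)), diag(4))

  ok <- matrix(c(1, .5, .5, 1), 2)
  expect_identical(repair_psd(ok), ok)

  bad <- matrix(0.9, 3, 3)
  bad[1, 2] <- bad[2, 1] <- -0.9
  diag(bad) <- 1
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- repair_psd(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 3))
  expect_equal(fixed, t(fixed))
})

test_that("penalty path is log-spaced from lambda_max down to the ratio", {
  corr <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(lambda_path(corr, n_points = 3, min_ratio = 0.01),
               c(0.5, 0.05, 0.005))
  pth <- lambda_path(corr, n_points = 25, min_ratio = 0.05)
  expect_equal(pth[1], 0.5)
  expect_equal(pth[25], 0.5 * 0.05)
  expect_true(all(diff(pth) < 0))
  expect_warning(p0 <- lambda_path(diag(3)), "degenerate")
  expect_equal(p0, 0)
})

test_that("graphical lasso matches closed forms in degenerate cases", {
  expect_equal(unclass(graphical_lasso(diag(3), 0.2)), diag(3),
               ignore_attr = TRUE)

  S <- matrix(c(1, .6, .6, 1), 2)
  K <- graphical_lasso(S, 0)
  expect_equal(unclass(K), solve(S), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(precision_to_weights(K)[1, 2], 0.6, tolerance = 1e-8)

  # at lambda >= max |S_ij| the network is exactly empty
  K_empty <- graphical_lasso(S, 0.6)
  expect_equal(unclass(K_empty), diag(2), ignore_attr = TRUE)
})

test_that("graphical lasso attains the penalized-likelihood optimum (oracle)", {
  S3 <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, -0.3,
                 0.2, -0.3, 1), 3)
  S4 <- matrix(0.25, 4, 4)
  S4[1, 2] <- S4[2, 1] <- 0.6
  S4[3, 4] <- S4[4, 3] <- -0.45
  diag(S4) <- 1
  for (S in list(S3, S4)) {
    for (lam in c(0.05, 0.2)) {
      K_cd <- graphical_lasso(S, lam)
      K_or <- ista_glasso(S, lam)
      f_cd <- penalized_loglik(K_cd, S, lam)
      f_or <- penalized_loglik(K_or, S, lam)
      expect_lt(abs(f_cd - f_or), 1e-6)
    }
  }
})

test_that("precision-to-weights matches the residual-regression oracle", {
  expect_equal(precision_to_weights(diag(3)), matrix(0, 3, 3))
  K2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precision_to_weights(K2)[1, 2], 0.5)

  K3 <- matrix(c(2, -0.5, 0.3,
                 -0.5, 1.5, -0.4,
                 0.3, -0.4, 1.8), 3)
  W <- precision_to_weights(K3)
  Sigma <- solve(K3)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(W[pair[1], pair[2]],
                 residual_partial_cor(Sigma, pair[1], pair[2]),
                 tolerance = 1e-10)
  }
})

test_that("EBIC evaluates the stated formula", {
  expect_equal(ebic(diag(3), diag(3), n = 100), 300)
  # no-edge fits are gamma-invariant
  expect_equal(ebic(diag(5), diag(5), n = 50, gamma = 0),
               ebic(diag(5), diag(5), n = 50, gamma = 1))
  # one extra (negligible) edge costs log n + 4 gamma log p
  K0 <- diag(3)
  K1 <- K0; K1[1, 2] <- K1[2, 1] <- 1e-6
  S <- diag(3)
  d <- ebic(K1, S, n = 200, gamma = 0.5) - ebic(K0, S, n = 200, gamma = 0.5)
  expect_equal(d, log(200) + 4 * 0.5 * log(3), tolerance = 1e-3)
})

test_that("zero-penalty weights equal unregularized partial correlations", {
  net <- chain_network()
  tab <- simulate_items(net, n = 800, seed = 21)
  S <- repair_psd(spearman_matrix(tab))
  K <- graphical_lasso(S, 0, tol = 1e-8)
  W <- precision_to_weights(K)
  Kdir <- solve(unclass(S))
  Wdir <- -Kdir / tcrossprod(sqrt(diag(Kdir)))
  diag(Wdir) <- 0
  expect_equal(unname(W), unname(Wdir), tolerance = 1e-6)
})

test_that("model selection is an EBIC argmin with sparsity along the path", {
  net <- chain_network()
  tab <- simulate_items(net, n = 600, seed = 8)
  fit <- select_network(tab)
  expect_s3_class(fit, "symptom_network")
  expect_lte(fit$ebic, min(fit$path$ebic))
  expect_equal(fit$weights, t(fit$weights))
  expect_equal(diag(fit$weights), setNames(rep(0, 17), fit$node_names))
  expect_true(all(abs(fit$weights) < 1))
  # path endpoints: sparsest at lambda_max, densest at the smallest penalty
  expect_lte(fit$path$edges[1], fit$path$edges[nrow(fit$path)])
  expect_equal(fit$path$edges[1], 0)
})

test_that("null data yield an (almost) empty selected network", {
  tab <- sample_ordinal(diag(17), cached_thresholds(), n = 2000, seed = 31)
  fit <- select_network(tab[, -1])
  expect_lte(edge_count(fit), 2)
  expect_lt(max(abs(fit$weights)), 0.05)
})

test_that("a known sparse network is recovered from simulated ordinal data", {
  net <- chain_network()
  tab <- simulate_items(net, n = 2000, seed = 77)
  fit <- select_network(tab)
  true_w <- net$weights[upper.tri(net$weights)]
  est_w <- fit$weights[upper.tri(fit$weights)]
  strong <- which(abs(true_w) >= 0.25)
  expect_true(all(est_w[strong] != 0))
  nz <- which(true_w != 0)
  expect_gte(cor(true_w[nz], est_w[nz]), 0.9)
})
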