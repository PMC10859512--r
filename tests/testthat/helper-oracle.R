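# Independent oracle for the penalized Gaussian log-likelihood
#   f(K) = log det K - tr(S K) - lambda * sum_{i != j} |K_ij|
# maximized by proximal gradient ascent (ISTA) with backtracking.  This
# shares no code with the block coordinate-descent solver it checks.

penalized_loglik <- function(K, S, lambda) {
  determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K) -
    lambda * sum(abs(K[row(K) != col(K)]))
}

soft_offdiag <- function(K, t) {
  Ksh <- sign(K) * pmax(abs(K) - t, 0)
  diag(Ksh) <- diag(K)
  Ksh
}

ista_glasso <- function(S, lambda, iters = 20000, step = 0.1) {
  p <- nrow(S)
  K <- diag(p)
  f_old <- penalized_loglik(K, S, lambda)
  for (i in seq_len(iters)) {
    G <- solve(K) - S            # gradient of the smooth part
    t <- step
    repeat {
      Knew <- soft_offdiag(K + t * G, t * lambda)
      Knew <- (Knew + t(Knew)) / 2
      ev <- min(eigen(Knew, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-10) {
        f_new <- penalized_loglik(Knew, S, lambda)
        if (f_new >= f_old - 1e-14) break
      }
      t <- t / 2
      if (t < 1e-12) { Knew <- K; f_new <- f_old; break }
    }
    if (abs(f_new - f_old) < 1e-13 && i > 50) { K <- Knew; break }
    K <- Knew
    f_old <- f_new
  }
  K
}

# Partial correlation of variables i and j given the rest, from the
# covariance: correlation of the regression residuals of i and j on the
# remaining variables.  Used as the residual-regression oracle.
residual_partial_cor <- function(Sigma, i, j) {
  r <- setdiff(seq_len(nrow(Sigma)), c(i, j))
  Scond <- Sigma[c(i, j), c(i, j)] -
    Sigma[c(i, j), r, drop = FALSE] %*%
    solve(Sigma[r, r, drop = FALSE], Sigma[r, c(i, j), drop = FALSE])
  Scond[1, 2] / sqrt(Scond[1, 1] * Scond[2, 2])
}
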