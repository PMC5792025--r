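# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths: quadratic forms are evaluated with
# explicit projection matrices, rejection rates by brute-force simulation.

# Explicit design matrix X (N x K) of an allocation sequence.
design_matrix <- function(seq, K) {
  X <- matrix(0, length(seq), K)
  X[cbind(seq_along(seq), seq)] <- 1
  X
}

# Explicit projection matrices of the one-way ANOVA F statistic:
# A spans the between-group space, B the residual space.
projection_AB <- function(seq, K) {
  N <- length(seq)
  X <- design_matrix(seq, K)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  list(A = H - matrix(1 / N, N, N), B = diag(N) - H)
}

# Noncentrality parameters via the explicit matrices (independent of the
# package's column-sum formula).
oracle_noncentrality <- function(seq, K, b, eta) {
  ab <- projection_AB(seq, K)
  list(lambda1 = eta^2 * drop(t(b) %*% ab$A %*% b),
       lambda2 = eta^2 * drop(t(b) %*% ab$B %*% b))
}

# Brute-force rejection rate of the one-way F-test under y = mu[seq] + eta*b + eps,
# vectorized across `reps` simulated trials. Returns the empirical rate and
# its binomial standard error.
oracle_rejection_rate <- function(seq, K, b, eta, alpha, reps,
                                  mu = rep(0, K)) {
  N <- length(seq)
  m <- N / K
  shift <- mu[seq] + eta * b
  y <- matrix(rnorm(reps * N), reps, N) + matrix(shift, reps, N, byrow = TRUE)
  gsum <- vapply(seq_len(K), function(k) rowSums(y[, seq == k, drop = FALSE]),
                 numeric(reps))
  ssb <- rowSums(gsum^2) / m - rowSums(y)^2 / N
  sst <- rowSums(y^2) - rowSums(y)^2 / N
  Fst <- (ssb / (K - 1)) / ((sst - ssb) / (N - K))
  rate <- mean(Fst > qf(1 - alpha, K - 1, N - K))
  list(rate = rate, se = sqrt(rate * (1 - rate) / reps))
}

# Monte Carlo CDF of the doubly noncentral F at a point.
oracle_pdnf <- function(x, df1, df2, l1, l2, reps) {
  draws <- (rchisq(reps, df1, ncp = l1) / df1) / (rchisq(reps, df2, ncp = l2) / df2)
  p <- mean(draws <= x)
  list(p = p, se = sqrt(p * (1 - p) / reps))
}
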