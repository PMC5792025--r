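# Outcome generation, the unadjusted and bias-adjusted F-tests, and the
# power comparison between them.

test_that("generated outcomes follow y = mu[t] + eta*b + eps", {
  d <- pbd_design(3, c = 2, M = 1)
  s <- c(1L, 2L, 1L, 3L, 3L, 2L)
  b <- bias_vector(s, d, biasing_policy("II", c(2, 3), K = 3))
  mu <- c(0, 1, 2)
  y_det <- generate_outcomes(s, d, mu, eta = 0.5, b = b, sigma = 1e-9, seed = 1)
  expect_equal(y_det, mu[s] + 0.5 * b, tolerance = 1e-6)
  expect_identical(generate_outcomes(s, d, mu, eta = 1, b = b, seed = 2),
                   generate_outcomes(s, d, mu, eta = 1, b = b, seed = 2))
  # law of large numbers on the componentwise mean
  set.seed(3)
  reps <- 20000
  acc <- rowMeans(vapply(seq_len(reps), function(i)
    generate_outcomes(s, d, mu, eta = 2, b = b), numeric(6)))
  expect_lt(max(abs(acc - (mu[s] + 2 * b))), 4 / sqrt(reps) * 1.5)
  expect_error(generate_outcomes(s, d, mu, eta = 1), "'b' is required")
  expect_error(generate_outcomes(s, d, mu[1:2]), "length K")
  expect_error(generate_outcomes(s, d, mu, sigma = 0), "sigma")
})

test_that("unadjusted F-test equals the textbook ANOVA", {
  d <- pbd_design(3, c = 2, M = 1)
  s <- c(1L, 2L, 1L, 3L, 3L, 2L)
  y <- c(4.1, 2.8, 5.3, 1.2, 0.7, 3.0)
  res <- f_test_unadjusted(y, s, d)
  ref <- anova(lm(y ~ factor(s)))       # independent oracle
  expect_equal(res$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 3L)
  const <- f_test_unadjusted(rep(2.5, 6), s, d)
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("unadjusted size under eta = 0 is alpha, and under bias matches r(X)", {
  d <- pbd_design(3, c = 1, M = 4)
  s <- generate_pbd(d, seed = 40)
  b <- bias_vector(s, d, biasing_policy("I", 1, K = 3))
  set.seed(41)
  reps <- 40000
  or0 <- oracle_rejection_rate(s, 3, b, eta = 0, alpha = 0.05, reps = reps)
  expect_lt(abs(or0$rate - 0.05), 3 * or0$se)
  eta <- cohens_f(3, 4)
  orb <- oracle_rejection_rate(s, 3, b, eta = eta, alpha = 0.05, reps = reps)
  r <- rejection_probability(s, d, b, eta, 0.05)
  expect_lt(abs(orb$rate - r), 3 * orb$se)
})

test_that("adjusted test matches lm + extra sum of squares and estimates eta", {
  d <- pbd_design(3, c = 1, M = 4)
  set.seed(42)
  s <- generate_pbd(d)
  b <- bias_vector(s, d, biasing_policy("I", 1, K = 3))
  y <- generate_outcomes(s, d, mu = c(0, 0.5, 1), eta = 0.8, b = b, seed = 43)
  res <- f_test_adjusted(y, s, d, b)
  full <- lm(y ~ 0 + factor(s) + b)
  red <- lm(y ~ b)
  ref <- anova(red, full)                # independent oracle
  expect_equal(res$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$eta_hat, unname(coef(full)["b"]), tolerance = 1e-10)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 12L - 3L - 1L)
  expect_false(res$degenerate)
})

test_that("adjusted test falls back when b lies in the group span", {
  d <- pbd_design(3, c = 1, M = 4)
  set.seed(44)
  s <- generate_pbd(d)
  y <- rnorm(12)
  un <- f_test_unadjusted(y, s, d)
  for (b in list(rep(0, 12), rep(1, 12), as.numeric(s == 2))) {
    ad <- f_test_adjusted(y, s, d, b)
    expect_true(ad$degenerate)
    expect_equal(ad$statistic, un$statistic)
    expect_equal(ad$reject, un$reject)
  }
})

test_that("adjusted statistic is invariant to constant shifts of b", {
  d <- pbd_design(4, c = 2, M = 2)
  set.seed(45)
  s <- generate_pbd(d)
  b <- bias_vector(s, d, biasing_policy("II", c(1, 2), K = 4))
  y <- rnorm(d$N)
  r1 <- f_test_adjusted(y, s, d, b)
  r2 <- f_test_adjusted(y, s, d, b + 3)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("eta_hat recovers the true selection effect", {
  d <- pbd_design(3, c = 1, M = 8)
  set.seed(46)
  reps <- 3000
  eta_true <- 2
  pol <- biasing_policy("I", 1, K = 3)
  est <- vapply(seq_len(reps), function(i) {
    s <- generate_pbd(d)
    b <- bias_vector(s, d, pol)
    y <- generate_outcomes(s, d, mu = c(0, 0, 0), eta = eta_true, b = b)
    f_test_adjusted(y, s, d, b)$eta_hat
  }, numeric(1))
  est <- est[!is.na(est)]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - eta_true), 2 * se + 1e-3)
})

test_that("adjustment restores the size under the null with selection bias", {
  set.seed(47)
  reps <- 20000
  d <- selbias:::.design_for_scheme(3, 8, "PBD_K")
  pol <- biasing_policy("I", 1, K = 3)
  seqs <- selbias:::.generate_pbd_matrix(d, reps)
  bmat <- selbias:::.bias_matrix(seqs, pol)
  eta <- cohens_f(3, 8)
  y <- matrix(rnorm(reps * d$N), reps) + eta * bmat    # equal means, biased
  res <- selbias:::.batch_ftests(seqs, bmat, y, d, alpha = 0.05)
  size_adj <- mean(res$reject_adjusted)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(size_adj - 0.05), 3 * se)
  # the unadjusted test is inflated in the same setting
  expect_gt(mean(res$reject_unadjusted), 0.05 + 3 * se)
})

test_that("batch F-tests agree with the per-trial functions", {
  set.seed(48)
  d <- pbd_design(3, c = 2, M = 2)
  pol <- biasing_policy("I", 1, K = 3)
  seqs <- selbias:::.generate_pbd_matrix(d, 20)
  bmat <- selbias:::.bias_matrix(seqs, pol)
  y <- matrix(rnorm(20 * d$N), 20) + 0.9 * bmat
  res <- selbias:::.batch_ftests(seqs, bmat, y, d, alpha = 0.05)
  for (i in 1:20) {
    un <- f_test_unadjusted(y[i, ], seqs[i, ], d)
    ad <- f_test_adjusted(y[i, ], seqs[i, ], d, bmat[i, ])
    expect_equal(res$reject_unadjusted[i], un$reject)
    expect_equal(res$reject_adjusted[i], ad$reject)
    if (!ad$degenerate)
      expect_equal(res$eta_hat[i], ad$eta_hat, tolerance = 1e-9)
  }
})

test_that("power simulation: anchored at rho = 0, inflated without adjustment, flat with it", {
  pw <- power_simulation(3, 16, schemes = c("PBD_N", "PBD_N_HALF", "PBD_K"),
                         rho = c(0, 0.5, 1, 2), replicates = 6000, seed = 49)
  expect_equal(nrow(pw), 24L)
  un0 <- pw$power[pw$test == "unadjusted" & pw$rho == 0]
  expect_true(all(abs(un0 - 0.8) < 0.025))     # design power anchor
  for (sc in c("PBD_N", "PBD_N_HALF", "PBD_K")) {
    un <- pw[pw$test == "unadjusted" & pw$scheme == sc, ]
    expect_true(all(diff(un$power[order(un$rho)]) > -0.01))  # nondecreasing in rho
  }
  for (sc in c("PBD_N", "PBD_N_HALF")) {
    ad <- pw$power[pw$test == "adjusted" & pw$scheme == sc]
    expect_lte(max(ad) - min(ad), 0.03)        # flat in rho
  }
  # small blocks pay the largest adjustment price
  adj0 <- pw[pw$test == "adjusted" & pw$rho == 0, ]
  expect_lt(adj0$power[adj0$scheme == "PBD_K"],
            adj0$power[adj0$scheme == "PBD_N"])
  expect_error(power_simulation(3, 16, replicates = 0), "replicates")
})
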