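# Policy I/II bias vectors; the two printed worked examples are the
# authoritative anchors for the sign conventions.

worked_seq <- c(1L, 2L, 1L, 3L, 3L, 2L)
worked_design <- pbd_design(3, c = 2, M = 1)

test_that("policy specification is validated", {
  expect_error(biasing_policy("I", integer(0), K = 3), "proper subset")
  expect_error(biasing_policy("I", 1:3, K = 3), "proper subset")
  expect_error(biasing_policy("I", 4, K = 3), "proper subset")
  expect_error(biasing_policy("I", 1, K = 1), "K")
  expect_error(biasing_policy("I", 1, K = 3, direction = 2), "direction")
  expect_silent(biasing_policy("II", c(2, 3), K = 3))
})

test_that("worked examples: Policy I and II on the six-patient trial", {
  bI <- bias_vector(worked_seq, worked_design, biasing_policy("I", 1, K = 3))
  expect_equal(bI, c(0L, -1L, 0L, -1L, -1L, 0L))
  bII <- bias_vector(worked_seq, worked_design, biasing_policy("II", c(2, 3), K = 3))
  expect_equal(bII, c(0L, 1L, 1L, 1L, 1L, 1L))
  # reversed preference direction mirrors the vector
  bI_neg <- bias_vector(worked_seq, worked_design,
                        biasing_policy("I", 1, K = 3, direction = -1))
  expect_equal(bI_neg, -bI)
})

test_that("bias table lays out indicators, counts and bias values", {
  tab <- bias_table(worked_seq, worked_design, biasing_policy("I", 1, K = 3))
  expect_equal(names(tab), c("patient", "x_1", "x_2", "x_3", "N_1", "N_2", "N_3", "b"))
  expect_equal(tab$b, c(0L, -1L, 0L, -1L, -1L, 0L))
  expect_equal(unname(unlist(tab[4, c("N_1", "N_2", "N_3")])), c(2L, 1L, 0L))
  expect_equal(rowSums(tab[, c("x_1", "x_2", "x_3")]), rep(1, 6))
})

test_that("b_1 is always zero and entries stay in {-1,0,1}", {
  set.seed(20)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    d <- pbd_design(K, c = sample(1:2, 1), M = sample(1:3, 1))
    s <- generate_pbd(d)
    Fs <- sample.int(K, sample.int(K - 1, 1))
    for (kind in c("I", "II")) {
      b <- bias_vector(s, d, biasing_policy(kind, Fs, K))
      expect_identical(b[1], 0L)
      expect_true(all(b %in% c(-1L, 0L, 1L)))
    }
  }
})

test_that("Policy I is dominated by Policy II for the same favoured set", {
  set.seed(21)
  for (rep in 1:30) {
    K <- sample(3:6, 1)
    d <- pbd_design(K, c = sample(1:2, 1), M = sample(1:3, 1))
    s <- generate_pbd(d)
    Fs <- sample.int(K, sample.int(K - 1, 1))
    bI <- bias_vector(s, d, biasing_policy("I", Fs, K))
    bII <- bias_vector(s, d, biasing_policy("II", Fs, K))
    nz <- bI != 0L
    expect_equal(bI[nz], bII[nz])          # same nonzero values
    expect_true(all(abs(bI) <= abs(bII)))  # II biases at least as many patients
    expect_true(all(bI * bII >= 0))
  }
})

test_that("bias vectors are equivariant under consistent relabeling", {
  set.seed(22)
  for (rep in 1:20) {
    K <- sample(3:5, 1)
    d <- pbd_design(K, c = 1, M = 3)
    s <- generate_pbd(d)
    Fs <- sample.int(K, sample.int(K - 1, 1))
    perm <- sample.int(K)
    for (kind in c("I", "II")) {
      b <- bias_vector(s, d, biasing_policy(kind, Fs, K))
      b_perm <- bias_vector(perm[s], d, biasing_policy(kind, perm[Fs], K))
      expect_equal(b_perm, b)
    }
  }
})

test_that("swapping F and its complement negates Policy I", {
  set.seed(23)
  for (rep in 1:20) {
    K <- sample(3:5, 1)
    d <- pbd_design(K, c = sample(1:2, 1), M = 2)
    s <- generate_pbd(d)
    Fs <- sample.int(K, sample.int(K - 1, 1))
    b <- bias_vector(s, d, biasing_policy("I", Fs, K))
    b_swap <- bias_vector(s, d, biasing_policy("I", setdiff(1:K, Fs), K))
    expect_equal(b_swap, -b)
  }
})

test_that("two-arm case reduces to the Blackwell-Hodges convergence strategy", {
  d <- pbd_design(2, c = 2, M = 1)
  expect_equal(blackwell_hodges_bias(c(1, 2, 2, 1), d), c(0L, -1L, 0L, 1L))
  # at i = 4 of (1,1,2,2) arm 1 still leads (counts 2 vs 1), so b_4 = -1
  expect_equal(blackwell_hodges_bias(c(1, 1, 2, 2), d), c(0L, -1L, -1L, -1L))
  expect_error(blackwell_hodges_bias(c(1, 2, 3, 1, 2, 3), pbd_design(3, 2, 1)), "K = 2")
  set.seed(24)
  for (rep in 1:15) {
    d <- pbd_design(2, c = sample(1:3, 1), M = sample(1:3, 1))
    s <- generate_pbd(d)
    b <- blackwell_hodges_bias(s, d)
    counts <- group_counts(s, d)
    expect_equal(as.numeric(b),
                 unname(sign(counts[seq_len(d$N), 2] - counts[seq_len(d$N), 1])))
    # policies I and II coincide for K = 2, F = {1}
    expect_equal(b, bias_vector(s, d, biasing_policy("II", 1, K = 2)))
  }
})

test_that("Policy II minus-branch variant is stricter than the default", {
  set.seed(25)
  hit <- 0L
  for (rep in 1:40) {
    K <- sample(3:5, 1)
    d <- pbd_design(K, c = sample(1:2, 1), M = sample(2:3, 1))
    s <- generate_pbd(d)
    Fs <- sample.int(K, sample.int(K - 1, 1))
    b_def <- bias_vector(s, d, biasing_policy("II", Fs, K))
    b_var <- bias_vector(s, d, biasing_policy("II", Fs, K, variant = "strict_minus"))
    expect_equal(b_def[b_def >= 0L], b_var[b_def >= 0L])  # +1/0 branch unchanged
    expect_true(all(b_var[b_def == -1L] %in% c(-1L, 0L)))  # variant can only drop -1s
    hit <- hit + sum(b_def == -1L & b_var == 0L)
  }
  expect_gt(hit, 0L)  # the two readings genuinely differ somewhere
})
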