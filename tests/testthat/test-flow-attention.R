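# The dense oracle materialises the full interaction matrix
# G = phi(Q) phi(K)^T; every flow quantity then has a closed dense form
# (row sums, column sums, normalised row/column sums) against which the
# linear implementation is checked.

dense_G <- function(phiQ, phiK) tcrossprod(phiQ, phiK)

test_that("sigmoid map hits its closed-form values and stays in (0,1)", {
  expect_equal(nonneg_map(matrix(0)), matrix(0.5))
  expect_equal(nonneg_map(matrix(log(3))), matrix(0.75))
  M <- rand_mat(6, 4, 31)
  expect_equal(nonneg_map(M) + nonneg_map(-M), matrix(1, 6, 4))
  expect_true(all(nonneg_map(M) > 0 & nonneg_map(M) < 1))
  expect_error(nonneg_map(matrix(Inf)), "non-finite")
})

test_that("incoming and outgoing flows equal dense row/column sums", {
  # constant case: all entries 0.5, d = 4, m = 3 -> I_i = 3 * 4 * 0.25
  phiQ <- matrix(0.5, 5, 4); phiK <- matrix(0.5, 3, 4)
  expect_equal(incoming_flow(phiQ, phiK), rep(3, 5))
  expect_equal(outgoing_flow(matrix(0.5, 3, 4), matrix(0.5, 6, 4)),
               rep(3, 6))
  # single source / single sink
  phiK1 <- nonneg_map(rand_mat(1, 4, 32))
  phiQ5 <- nonneg_map(rand_mat(5, 4, 33))
  expect_equal(incoming_flow(phiQ5, phiK1), drop(phiQ5 %*% t(phiK1)))
  expect_equal(outgoing_flow(phiK1, phiQ5), drop(phiQ5 %*% t(phiK1)))
  # random seeded vs dense
  phiQ <- nonneg_map(rand_mat(5, 4, 34))
  phiK <- nonneg_map(rand_mat(6, 4, 35))
  G <- dense_G(phiQ, phiK)
  expect_equal(incoming_flow(phiQ, phiK), rowSums(G), tolerance = 1e-12)
  expect_equal(outgoing_flow(phiQ, phiK), colSums(G), tolerance = 1e-12)
  expect_true(all(incoming_flow(phiQ, phiK) > 0))
  expect_error(incoming_flow(phiQ, phiK[, 1:3]), "dimensions differ")
})

test_that("competition matches the dense normalised column sums", {
  phiQ <- nonneg_map(rand_mat(6, 4, 36))
  phiK <- nonneg_map(rand_mat(6, 4, 37))
  V <- rand_mat(6, 4, 38)
  I <- incoming_flow(phiQ, phiK)
  cmp <- competition(phiQ, phiK, V, I)
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)
  G <- dense_G(phiQ, phiK)
  expect_equal(cmp$O_prime, colSums(G / I), tolerance = 1e-12)
  # constant inputs -> uniform softmax -> V' = V / m
  phiC <- matrix(0.3, 5, 4)
  cmpC <- competition(phiC, phiC, V[1:5, ], incoming_flow(phiC, phiC))
  expect_equal(cmpC$V_prime, V[1:5, ] / 5, tolerance = 1e-12)
  expect_error(competition(phiQ, phiK, V, c(-1, I[-1])),
               "conservation violation")
})

test_that("allocation matches the dense evaluation and annihilates V' = 0", {
  phiQ <- nonneg_map(rand_mat(8, 16, 39))
  phiK <- nonneg_map(rand_mat(8, 16, 40))
  V <- rand_mat(8, 16, 41)
  I <- incoming_flow(phiQ, phiK)
  O <- outgoing_flow(phiQ, phiK)
  Vp <- competition(phiQ, phiK, V, I)$V_prime
  R <- allocation(phiQ, phiK, Vp, O, I)
  G <- dense_G(phiQ, phiK)
  I_prime <- rowSums(sweep(G, 2, O, `/`))
  R_dense <- (1 / (1 + exp(-I_prime))) * ((G / I) %*% Vp)
  expect_lt(max(abs(R - R_dense)), 1e-5)
  expect_true(all(allocation(phiQ, phiK, Vp * 0, O, I) == 0))
  expect_error(allocation(phiQ, phiK, Vp, c(0, O[-1]), I),
               "conservation violation")
})

test_that("singleton token reduces to the hand closed form", {
  phiQ <- matrix(c(0.6, 0.2), 1, 2)
  phiK <- matrix(c(0.5, 0.4), 1, 2)
  V <- matrix(c(2, -1), 1, 2)
  I <- incoming_flow(phiQ, phiK)   # 0.6*0.5 + 0.2*0.4 = 0.38
  O <- outgoing_flow(phiQ, phiK)   # same scalar
  expect_equal(drop(I), 0.38)
  cmp <- competition(phiQ, phiK, V, I)
  expect_equal(cmp$weights, 1)     # softmax of a singleton
  expect_equal(cmp$V_prime, V)
  R <- allocation(phiQ, phiK, cmp$V_prime, O, I)
  # I' = (phiQ . phiK) / O = 1; gate = sigmoid(1); (G/I) V' = V
  expect_equal(R, (1 / (1 + exp(-1))) * V, tolerance = 1e-12)
})

test_that("linear forward equals the dense oracle on 20 seeded cases", {
  cfg <- flow_attention_config(hid_dim = 16, num_heads = 4, dropout = 0)
  worst <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(2:64, 1)
    d_in <- sample(4:12, 1)
    w <- flow_attention_init(d_in, cfg)
    X <- matrix(rnorm(n * d_in, sd = 2), n, d_in)
    diff <- max(abs(flow_attention_forward(X, w, cfg) -
                      dense_flow_attention_oracle(X, w, cfg)))
    worst <- max(worst, diff)
  }
  expect_lt(worst, 1e-5)
})

test_that("conservation identities hold in both formulations", {
  set.seed(43)
  phiQ <- nonneg_map(rand_mat(10, 6, 44))
  phiK <- nonneg_map(rand_mat(12, 6, 45))
  G <- dense_G(phiQ, phiK)
  I <- incoming_flow(phiQ, phiK)
  O <- outgoing_flow(phiQ, phiK)
  # inflow conservation: I' via normalised keys, dense vs linear
  I_lin <- drop(phiQ %*% colSums(phiK / O))
  expect_lt(max(abs(I_lin - rowSums(sweep(G, 2, O, `/`)))), 1e-6)
  # outflow conservation: O' via normalised queries, dense vs linear
  O_lin <- drop(phiK %*% colSums(phiQ / I))
  expect_lt(max(abs(O_lin - colSums(G / I))), 1e-6)
  # with all sources normalised, total dense flow equals n and m resp.
  expect_equal(sum(G / I), 10, tolerance = 1e-6)
  expect_equal(sum(sweep(G, 2, O, `/`)), 12, tolerance = 1e-6)
  # softmax over sources is a probability vector
  w <- competition(phiQ, phiK, rand_mat(12, 4, 46), I)$weights
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_true(all(w > 0))
})

test_that("forward output stays finite for extreme inputs", {
  cfg <- flow_attention_config(hid_dim = 8, num_heads = 2, dropout = 0)
  w <- flow_attention_init(4, cfg)
  X <- matrix(c(-50, 50, 0.001, -1e3), 8, 4)
  expect_true(all(is.finite(flow_attention_forward(X, w, cfg))))
  expect_error(flow_attention_forward(matrix(NA_real_, 2, 4), w, cfg),
               "non-finite")
})

test_that("multiply-add count grows linearly for the flow form, quadratically for the dense oracle", {
  cfg <- flow_attention_config(hid_dim = 16, num_heads = 4, dropout = 0)
  w <- flow_attention_init(8, cfg)
  ns <- c(16L, 32L, 64L, 128L)
  ops_lin <- ops_dense <- numeric(length(ns))
  for (i in seq_along(ns)) {
    X <- rand_mat(ns[i], 8, 50 + i)
    ops_lin[i] <- attr(flow_attention_forward(X, w, cfg,
                                              count_ops = TRUE), "ops")
    ops_dense[i] <- attr(dense_flow_attention_oracle(X, w, cfg,
                                                     count_ops = TRUE),
                         "ops")
  }
  r2 <- suppressWarnings(summary(lm(ops_lin ~ ns))$r.squared)
  expect_gt(r2, 0.99)
  # doubling n doubles linear cost but quadruples the dominant dense cost
  expect_lt(ops_lin[4] / ops_lin[3], 2.05)
  expect_gt(ops_dense[4] / ops_dense[3], 3)
})

test_that("configuration invariants are enforced", {
  expect_error(flow_attention_config(hid_dim = 45, num_heads = 4),
               "divisible")
  expect_error(flow_attention_config(dropout = 1), "dropout")
  expect_silent(flow_attention_config())
})
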