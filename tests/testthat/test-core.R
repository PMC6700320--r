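test_that("column normalization rescales and rejects degenerate columns", {
  expect_equal(normalize_columns(matrix(c(2, 2), 2, 1)), matrix(0.5, 2, 1))
  expect_equal(normalize_columns(matrix(c(1, 0), 2, 1)),
               matrix(c(1, 0), 2, 1))
  got <- normalize_columns(matrix(c(1.01, 1.0, 0.99), 3, 1))
  expect_equal(round(as.vector(got), 5), c(0.33667, 0.33333, 0.33000))
  expect_error(normalize_columns(matrix(c(1, 0, 0, 0), 2, 2)),
               "degenerate column")
  expect_error(normalize_columns(matrix(c(-1, 2), 2, 1)), "non-negative")
})

test_that("spike draws follow the distribution and the seed", {
  expect_true(all(replicate(20, draw_spike(c(0, 0, 1, 0))) == 3L))
  expect_identical(draw_spike(c(0, 0, 0)), NA_integer_)
  set.seed(42)
  draws <- replicate(10000, draw_spike(c(0.5, 0.5)))
  freq1 <- mean(draws == 1L)
  sigma <- sqrt(0.25 / 10000)
  expect_lt(abs(freq1 - 0.5), 3 * sigma)
  set.seed(7); a <- replicate(50, draw_spike(c(0.2, 0.3, 0.5)))
  set.seed(7); b <- replicate(50, draw_spike(c(0.2, 0.3, 0.5)))
  expect_identical(a, b)
})

test_that("h-dynamic matches its closed form on hand-checked cases", {
  W <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE)  # rows: inputs
  # one-hot latent state is absorbing
  expect_equal(h_update(c(1, 0), 1L, W, 0.5), c(1, 0))
  # uniform likelihood leaves any h unchanged
  Wu <- matrix(0.5, 2, 2)
  h <- c(0.3, 0.7)
  expect_equal(h_update(h, 2L, Wu, 0.3), h, tolerance = 1e-14)
  # direct evaluation
  got <- h_update(c(0.5, 0.5), 1L, cbind(c(0.8, 0.2), c(0.2, 0.8)), 0.1)
  expect_equal(got, c(0.58, 0.52) / 1.1, tolerance = 1e-14)
  expect_error(h_update(c(1, 0), 1L, matrix(c(0, 1, 0, 1), 2, 2), 0.1),
               "degenerate support")
})

test_that("h-dynamic preserves normalization and zero components", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    m <- sample(2:8, 1)
    h <- random_prob(n)
    if (i %% 3 == 0) h[sample.int(n, 1)] <- 0  # plant exact zeros
    h <- if (sum(h) > 0) h / sum(h) else random_prob(n)
    W <- random_weights(m, n)
    s <- sample.int(m, 1)
    eps <- runif(1, 0.01, 1)
    h2 <- h_update(h, s, W, eps)
    worst <- max(worst, abs(sum(h2) - 1))
    expect_true(all(h2[h == 0] == 0))
    expect_true(all(h2 >= 0))
  }
  expect_lt(worst, 1e-12)
})

test_that("identity-weight convergence follows the exact geometric law", {
  # constant spike s0 through identity weights: off-target mass decays as
  # (1 - h0(s0)) * (1 + eps)^-T
  eps <- 0.1
  n <- 5L
  h <- rep(1 / n, n)
  W <- diag(n)
  for (T in 1:50) {
    h <- h_update(h, 2L, W, eps)
    expect_equal(1 - h[2L], (1 - 1 / n) * (1 + eps)^-T, tolerance = 1e-10)
  }
})

test_that("reconstruction is the weighted mixture of weight columns", {
  W <- cbind(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(reconstruct(c(0.5, 0.5), W), c(0.5, 0.5))
  expect_equal(reconstruct(c(0, 1), W), c(0.2, 0.8))
  h <- random_prob(3)
  expect_equal(reconstruct(h, diag(3)), h)
})

test_that("cross-entropy and KL behave as information measures", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_identical(cross_entropy(c(1, 0), c(0, 1)), Inf)
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(5)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    p <- random_prob(n); q <- random_prob(n)
    expect_gte(kl_divergence(p, q), 0)
    # cross-entropy exceeds the entropy of p unless q matches p
    expect_gte(cross_entropy(p, q) - cross_entropy(p, p), 0)
  }
})

test_that("spike-count estimation recovers the source distribution", {
  expect_equal(estimate_p_from_spikes(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(estimate_p_from_spikes(4L, 4), c(0, 0, 0, 1))
  expect_error(estimate_p_from_spikes(integer(0), 2), "degenerate")
  set.seed(9)
  draws <- replicate(1000, draw_spike(c(0.9, 0.1)))
  p_hat <- estimate_p_from_spikes(draws, 2)
  expect_lt(abs(p_hat[1] - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
})

test_that("on/off encoding rectifies around mid-gray", {
  expect_equal(on_off_encode(1), cbind(on = 1, off = 0))
  expect_equal(on_off_encode(0), cbind(on = 0, off = 1))
  enc <- on_off_encode(0.5)
  expect_equal(as.vector(enc), c(0, 0))
  expect_true(is_degenerate(as.vector(enc)))
  # at most one channel positive, for any intensity
  enc <- on_off_encode(seq(0, 1, by = 0.05))
  expect_true(all(rowSums(enc > 0) <= 1))
})
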