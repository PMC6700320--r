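test_that("valid-convolution geometry reproduces the deep architecture", {
  net <- build_deep_conv_network()
  grids <- lapply(net$grids, as.integer)
  expect_equal(grids, list(c(28L, 28L), c(24L, 24L), c(12L, 12L),
                           c(8L, 8L), c(4L, 4L), c(1L, 1L), c(1L, 1L)))
  npp <- vapply(net$specs, function(s) s$neurons, 1L)
  expect_equal(npp, c(2L, 32L, 32L, 64L, 64L, 1024L, 10L))
  # the fully connected population sees all 16 pooled populations
  h5 <- which(net$pops$layer == 6L)
  expect_length(h5, 1L)
  expect_equal(sum(net$conns$target == h5), 16L)
  # pooling groups are fixed, shared groups hold one matrix each
  expect_false(net$trainable[["W_H1_H2"]])
  expect_false(net$trainable[["W_H3_H4"]])
  expect_length(net$weights, 6L)
  expect_error(build_feedforward(list(
    layer_spec("input", neurons = 2L, grid = c(3L, 3L)),
    layer_spec("conv", neurons = 4L, kernel = c(5L, 5L)),
    layer_spec("output", neurons = 2L))), "kernel larger")
})

test_that("pooling weights are feature-block matrices", {
  W <- build_pooling_weights(2, 4)
  expect_equal(dim(W), c(8L, 2L))
  expect_equal(colSums(W), c(1, 1))
  expect_equal(sum(W == 0.25), 8L)
  # inputs from different features never mix
  for (k in 0:3) expect_equal(W[k * 2 + 1:2, ], diag(2) * 0.25)
  expect_equal(build_pooling_weights(1, 1), matrix(1, 1, 1))
  expect_equal(colSums(build_pooling_weights(32, 4)), rep(1, 32))
  # permutation equivariance under feature relabeling
  F_ <- 5L; A <- 3L
  W <- build_pooling_weights(F_, A)
  perm <- sample.int(F_)
  row_perm <- as.vector(outer(perm, (seq_len(A) - 1L) * F_, "+"))
  expect_equal(W[row_perm, perm], W, ignore_attr = TRUE)
})

test_that("epsilon follows the per-layer divisor and the spike schedule", {
  expect_equal(effective_epsilon(epsilon_setting(0.1, divisor = 25)), 0.004)
  sched <- epsilon_setting(0.1, divisor = 1, breakpoint = 1000,
                           post_divisor = 25)
  expect_equal(effective_epsilon(sched, 0), 0.1)
  expect_equal(effective_epsilon(sched, 999), 0.1)
  expect_equal(effective_epsilon(sched, 1000), 0.004)
  expect_equal(effective_epsilon(epsilon_setting(0.1, divisor = 4)), 0.025)
})

test_that("random weight initialization stays near uniform columns", {
  set.seed(3)
  W0 <- init_weights_random(5, 3, scale = 0)
  expect_equal(W0, matrix(0.2, 5, 3))
  W <- init_weights_random(4, 50)
  expect_true(all(W >= 1 / (4 * 1.01) - 1e-12))
  expect_true(all(W >= 0.2475 & W <= 0.2525))
  expect_lt(max(abs(colSums(W) - 1)), 1e-12)
})

test_that("latent reset gives uniform distributions per population", {
  net <- build_parity_network(split = TRUE)
  h <- reset_latent(net)
  expect_null(h[[net$input_pops[1]]])
  sizes <- net$pops$n[!net$pops$is_input]
  vals <- h[!net$pops$is_input]
  for (i in seq_along(vals)) {
    expect_equal(vals[[i]], rep(1 / sizes[i], sizes[i]))
  }
})

test_that("a single population driven through identity weights converges
           at the closed-form geometric rate", {
  net <- build_feedforward(list(
    layer_spec("input", neurons = 4L, name = "X"),
    layer_spec("output", neurons = 4L, name = "HY")))
  net$weights[[1]] <- diag(4)
  set.seed(1)
  for (T in c(10L, 100L)) {
    rec <- simulate_pattern(net, list(c(0, 0, 1, 0)), T)
    h <- rec$h[[net$output_pop]]
    expect_equal(1 - h[3], 0.75 * 1.1^-T, tolerance = 1e-10)
  }
})

test_that("simulation draws one spike per emitting population per step", {
  net <- build_xor_network()
  ds <- make_xor_dataset()
  set.seed(2)
  rec <- simulate_pattern(net, ds$inputs[[1]], 100)
  expect_equal(rec$spikes_emitted, c(100L, 100L, 0L))  # X, H1, not HY
  net5 <- build_parity_network(split = TRUE)
  set.seed(2)
  rec5 <- simulate_pattern(net5, make_parity_dataset(TRUE)$inputs[[1]], 50)
  expect_equal(sum(rec5$spikes_emitted), 5L * 50L)
})

test_that("simulation is reproducible and records valid distributions", {
  net <- build_parity_network(split = TRUE)
  ds <- make_parity_dataset(TRUE)
  set.seed(11); a <- simulate_batch(net, ds$inputs[1:3], 200)
  set.seed(11); b <- simulate_batch(net, ds$inputs[1:3], 200)
  expect_identical(a, b)
  for (rec in a) {
    for (snap in rec$history) {
      for (h in snap) {
        expect_true(all(h >= 0))
        expect_lt(abs(sum(h) - 1), 1e-12)
      }
    }
  }
})

test_that("argmax decoding breaks ties toward the lowest index", {
  expect_equal(decode_output(c(0.2, 0.8)), 2L)
  expect_equal(decode_output(c(0.5, 0.5)), 1L)
  expect_equal(decode_output(replace(numeric(10), 8, 1)), 8L)
})
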