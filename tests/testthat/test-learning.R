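test_that("output backward error scales target/output mismatch", {
  expect_equal(phi_output(c(1, 0), c(1, 0) + c(0, 1e-12), 0.1)[1],
               (0.1 / 1.1), tolerance = 1e-9)
  expect_equal(phi_output(c(0, 1), c(0.5, 0.5), 0.1),
               c(0, 0.2 / 1.1))
  expect_equal(phi_output(c(1, 0), c(1, 0), 0.1), c(1 / 11, 0))
  # zeta(q) = 0 forces Phi(q) = 0 regardless of h
  phi <- phi_output(c(0.5, 0.5, 0), random_prob(3), 0.2)
  expect_equal(phi[3], 0)
})

test_that("backward recursion collapses for identity weights and
           matches a naive triple loop", {
  eps <- 0.1
  phi_n <- c(0.3, 0.7, 0.1)
  expect_equal(phi_backstep(phi_n, rep(1 / 3, 3), diag(3), eps),
               (eps / (1 + eps)) * phi_n)
  expect_equal(phi_backstep(numeric(3), random_prob(3),
                            random_weights(4, 3), eps), numeric(4))
  set.seed(21)
  for (i in 1:20) {
    W <- random_weights(3, 3)
    h <- random_prob(3)
    phi_n <- runif(3)
    got <- phi_backstep(phi_n, h, W, eps)
    want <- numeric(3)
    for (q in 1:3) {
      den <- 0; num <- 0
      for (j in 1:3) den <- den + h[j] * W[q, j]
      for (qp in 1:3) num <- num + phi_n[qp] * h[qp] * W[q, qp]
      want[q] <- (eps / (1 + eps)) * num / den
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("r, R, F satisfy their defining identities", {
  out <- compute_rRF(rep(0.25, 4), rep(0.25, 4), diag(4))
  expect_equal(out$r, diag(4) * 0.25)
  expect_equal(out$R, rep(0.25, 4))
  W <- random_weights(3, 4)
  h_post <- c(0, 0, 1, 0)
  out <- compute_rRF(random_prob(3), h_post, W)
  expect_equal(out$R, W[, 3])
  set.seed(31)
  for (i in 1:25) {
    W <- random_weights(sample(2:6, 1), sample(2:6, 1))
    out <- compute_rRF(random_prob(nrow(W)), random_prob(ncol(W)), W)
    expect_equal(sum(out$R), 1, tolerance = 1e-12)
  }
})

test_that("omega vanishes for constant Phi and matches a naive loop", {
  set.seed(41)
  W <- random_weights(4, 3)
  parts <- compute_rRF(random_prob(4), random_prob(3), W)
  expect_equal(omega(parts$F, parts$R, parts$r, rep(0.37, 3)),
               matrix(0, 4, 3), tolerance = 1e-14)
  expect_equal(omega(parts$F, parts$R, parts$r, numeric(3)),
               matrix(0, 4, 3))
  phi <- runif(3)
  got <- omega(parts$F, parts$R, parts$r, phi)
  want <- matrix(0, 4, 3)
  for (q in 1:4) for (qp in 1:3) {
    acc <- 0
    for (j in 1:3) {
      acc <- acc + (parts$R[q] * (j == qp) - parts$r[q, j]) * phi[j]
    }
    want[q, qp] <- parts$F[q, qp] * acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("batch gradient is additive over patterns", {
  set.seed(51)
  net <- build_xor_network()
  ds <- make_xor_dataset()
  recs <- simulate_batch(net, ds$inputs, 256)
  acc_all <- accumulate_gradient(recs, ds$targets, net)
  # external per-pattern recomputation, summed by hand
  by_hand <- lapply(acc_all$grads, function(g) g * 0)
  for (i in 1:4) {
    one <- accumulate_gradient(recs[i], ds$targets[i], net)
    for (g in names(by_hand)) by_hand[[g]] <- by_hand[[g]] + one$grads[[g]]
  }
  for (g in names(by_hand)) {
    expect_lt(max(abs(acc_all$grads[[g]] - by_hand[[g]])), 1e-12)
  }
  # duplicated pattern doubles the gradient (sum mode)
  two <- accumulate_gradient(recs[c(1, 1)], ds$targets[c(1, 1)], net,
                             mode = "sum")
  one <- accumulate_gradient(recs[1], ds$targets[1], net, mode = "sum")
  for (g in names(one$grads)) {
    expect_lt(max(abs(two$grads[[g]] - 2 * one$grads[[g]])), 1e-14)
  }
})

test_that("vectorized gradient equals the naive loop oracle", {
  set.seed(61)
  for (i in 1:12) {
    net <- if (i %% 3 == 0) random_shared_network() else
      random_micro_network()
    ds <- random_dataset_for(net, 1L)
    recs <- simulate_batch(net, ds$inputs, 30)
    for (mode in c("average", "sum")) {
      fast <- accumulate_gradient(recs, ds$targets, net, mode = mode)
      slow <- gradient_oracle_naive(recs[[1]], ds$targets[[1]], net,
                                    mode = mode)
      for (g in names(fast$grads)) {
        expect_lt(max(abs(fast$grads[[g]] - slow$grads[[g]])), 1e-10)
      }
    }
  }
})

test_that("retardation-off mode uses the final snapshot but keeps shapes
           and normalization", {
  set.seed(71)
  net <- build_parity_network(split = TRUE)
  ds <- make_parity_dataset(TRUE)
  recs <- simulate_batch(net, ds$inputs[1:4], 12)
  on <- accumulate_gradient(recs, ds$targets[1:4], net, retarded = TRUE)
  off <- accumulate_gradient(recs, ds$targets[1:4], net, retarded = FALSE)
  slow_off <- gradient_oracle_naive(recs[[1]], ds$targets[[1]], net,
                                    retarded = FALSE)
  one_off <- accumulate_gradient(recs[1], ds$targets[1], net,
                                 retarded = FALSE)
  for (g in names(on$grads)) {
    expect_equal(dim(on$grads[[g]]), dim(off$grads[[g]]))
    expect_lt(max(abs(one_off$grads[[g]] - slow_off$grads[[g]])), 1e-10)
  }
  g_out <- "W_H2_HY"
  rel <- max(abs(on$grads[[g_out]] - off$grads[[g_out]])) /
    max(abs(on$grads[[g_out]]))
  expect_gt(rel, 1e-3)
})

test_that("multiplicative update respects non-negativity, the floor and
           normalization", {
  set.seed(81)
  W <- random_weights(4, 3)
  expect_identical(multiplicative_update(W, matrix(0, 4, 3), 0.025), W)
  g <- matrix(rnorm(12), 4, 3)
  for (gamma in c(0.025, 0.5, 0.99)) {
    W2 <- multiplicative_update(W, g, gamma)
    expect_true(all(W2 >= 0))
    expect_lt(max(abs(colSums(W2) - 1)), 1e-12)
  }
  # an entry pushed exactly to zero at gamma = 1 is caught by the floor
  W <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  g <- matrix(c(-1, 0, 0, 0), 2, 2)  # -dE/dW: entry (1,1) has dE/dW = +S
  W2 <- multiplicative_update(W, g, 1, theta = 1e-4)
  expect_equal(W2[1, 1], 1e-4 / (1e-4 + 0.5), tolerance = 1e-12)
})

test_that("learning reduces the XOR objective in most seeded runs", {
  ds <- make_xor_dataset()
  improved <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    net <- build_xor_network()
    fit <- train_simple(net, ds, training_schedule(
      schedule_stage(10, 1024, 0.025)))
    if (fit$log$objective[10] < fit$log$objective[1]) improved <- improved + 1L
  }
  expect_gte(improved, 8L)
})

test_that("zero learning rate leaves weights untouched but logs the step", {
  set.seed(91)
  net <- build_xor_network()
  ds <- make_xor_dataset()
  fit <- train_simple(net, ds, training_schedule(schedule_stage(1, 64, 0)))
  expect_identical(fit$net$weights, net$weights)
  expect_equal(nrow(fit$log), 1L)
  expect_true(is.finite(fit$log$objective))
})

test_that("the stage learning-rate rule halves on schedule", {
  g <- gamma_halving(0.03, 1000)
  expect_equal(g(1), 0.03)
  expect_equal(g(999), 0.03)
  expect_equal(g(1000), 0.015)
  expect_equal(g(1999), 0.015)
  expect_equal(g(6500), 0.03 / 64)
})
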