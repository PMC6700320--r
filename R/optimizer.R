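# Mini-batch optimizer for SbS networks.
#
# Plain gradient descent on SbS weights is prone to poor optima; this
# optimizer smooths the gradients and the output Kullback-Leibler
# divergence over mini-batches with bias-corrected exponential averages,
# modulates the learning rate by the square root of the normalized KL, and
# applies an additive update on the Z-transformed gradient with floor rules
# that respect the non-negativity and normalization constraints.

#' Bias-corrected exponentially smoothed quantity
#'
#' Maintains `Yhat(L) = Yhat(L-1)(1 - 1/tau) + Y(L)/tau` and the
#' bias-corrected value `Ystar(L) = Yhat(L) / (1 - (1 - 1/tau)^L)`, which
#' is exact for a constant input sequence at every step and equals the raw
#' value at the first step.
#'
#' @param tau Smoothing time constant in update steps (>= 1).
#' @return An object of class `smoothed_quantity` with `value()` initially
#'   undefined (`L = 0`).
#' @export
smoothed_quantity <- function(tau) {
  stopifnot(tau >= 1)
  structure(list(tau = tau, L = 0L, yhat = 0), class = "smoothed_quantity")
}

#' Advance a smoothed quantity by one observation
#'
#' @param q A [smoothed_quantity()].
#' @param Y New raw observation (scalar or matrix; shape must be constant).
#' @return The updated object; the bias-corrected estimate is in `$star`.
#' @export
smooth_update <- function(q, Y) {
  a <- 1 - 1 / q$tau
  q$L <- q$L + 1L
  q$yhat <- q$yhat * a + Y / q$tau
  q$star <- q$yhat / (1 - a^q$L)
  q
}

#' KL-modulated learning rate
#'
#' Tracks the running maximum of the smoothed output divergence and returns
#' `gamma = gamma0 * sqrt(KL*/KLmax)`: the rate starts at `gamma0` and
#' decays as training closes the gap to the targets, recovering whenever
#' the divergence rises to a new maximum.
#'
#' @param state Optimizer state list with `gamma0` and `kl_max`.
#' @param kl_star Current bias-corrected smoothed KL divergence.
#' @return List with updated `state` and the learning rate `gamma`.
#' @export
learning_rate <- function(state, kl_star) {
  state$kl_max <- max(state$kl_max, kl_star)
  gamma <- if (state$kl_max <= 0) 0 else
    state$gamma0 * sqrt(kl_star / state$kl_max)
  list(state = state, gamma = gamma)
}

#' Z-transform of a gradient
#'
#' `Z = (-dE/dW) * W` elementwise: scaling the gradient by the current
#' weight turns the additive update into one whose relative step size is
#' bounded, matching the multiplicative geometry of the weights.
#'
#' @param grad Accumulated negative gradient `-dE/dW`.
#' @param W Weight matrix.
#' @return Matrix `Z` of the same shape.
#' @export
z_transform <- function(grad, W) grad * W

#' Additive optimizer update with floor rules
#'
#' `V = W + (gamma/S) Z*` with `S = min(max|Z*|, 1)` per weight group,
#' floored elementwise at both `theta` and `W/2` (no weight loses more than
#' half its value per step), then column-normalized.  `S = 0` is a no-op.
#'
#' @param W Weight matrix.
#' @param Z_star Smoothed Z-transformed gradient for this group.
#' @param gamma Learning rate.
#' @param theta Weight floor (default 1e-4).
#' @return Updated, column-normalized weight matrix.
#' @export
optimized_update <- function(W, Z_star, gamma, theta = 1e-4) {
  S <- min(max(abs(Z_star)), 1)
  if (S == 0) return(W)
  V <- W + (gamma / S) * Z_star
  normalize_columns(pmax(V, theta, W / 2))
}

#' Dropout by latent-variable initialization
#'
#' Draws a random subset of neurons (each enabled independently with
#' probability `beta`) and returns an initial latent vector that is uniform
#' over the enabled neurons and exactly zero elsewhere.  Because the
#' h-dynamic is multiplicative, disabled neurons stay silent for the whole
#' pattern presentation.  An all-disabled draw is redrawn.
#'
#' @param n_neurons Population size.
#' @param beta Fraction of enabled neurons in (0, 1].
#' @return Initial latent probability vector.
#' @export
dropout_init <- function(n_neurons, beta) {
  stopifnot(beta > 0, beta <= 1)
  repeat {
    on <- runif(n_neurons) <= beta
    if (any(on)) break
  }
  on / sum(on)
}

#' One stage of an optimized training run
#'
#' @param n_batches Number of mini-batches to process.
#' @param spikes Spikes per pattern.
#' @param reset_groups Weight groups re-randomized at the start of the
#'   stage.
#' @param train_groups Weight groups updated during the stage (default:
#'   all trainable groups).
#' @param dropout Optional list `list(layer =, beta0 =, double_every =)`:
#'   dropout-by-initialization on the named layer, starting with fraction
#'   `beta0` enabled and doubling every `double_every` mini-batches until 1.
#' @param eps Optional [epsilon_setting()] overriding the network's for
#'   this stage.
#' @param name Optional stage label.
#' @return A stage description list.
#' @export
optimizer_stage <- function(n_batches, spikes = 1200L, reset_groups = NULL,
                            train_groups = NULL, dropout = NULL, eps = NULL,
                            name = NULL) {
  list(n_batches = as.integer(n_batches), spikes = as.integer(spikes),
       reset_groups = reset_groups, train_groups = train_groups,
       dropout = dropout, eps = eps, name = name)
}

#' Train a network with the mini-batch optimizer
#'
#' Per mini-batch: sample a fraction of the training patterns without
#' replacement, simulate them (with per-pattern dropout initialization if
#' configured), accumulate the backprop gradient, Z-transform it, smooth Z
#' and the output KL divergence with bias-corrected exponential averages,
#' derive the KL-modulated learning rate, and apply the additive update
#' with floor rules to the stage's trainable groups.  Smoothing state and
#' the running KL maximum reset at stage boundaries.
#'
#' @param net An `sbs_network`.
#' @param dataset A `pattern_set`.
#' @param stages List of [optimizer_stage()]s.
#' @param mini_frac Mini-batch size as a fraction of the dataset.
#' @param tau Smoothing constant (default 10, matching 10% mini-batches).
#' @param gamma0 Base learning rate (default 0.05).
#' @param theta Weight floor.
#' @param retarded Use time-retarded snapshots in the learning rule.
#' @param callback Optional `function(net, log_row)` after each mini-batch.
#' @return List with the trained `net` and a data-frame `log` (stage,
#'   batch, gamma, kl, kl_star, beta, train_error).
#' @export
train_optimized <- function(net, dataset, stages, mini_frac = 0.1,
                            tau = 10, gamma0 = 0.05, theta = 1e-4,
                            retarded = TRUE, callback = NULL) {
  n_pat <- length(dataset$inputs)
  batch_size <- max(1L, round(mini_frac * n_pat))
  log <- list()
  truth <- vapply(dataset$targets, which.max, 1L)

  for (si in seq_along(stages)) {
    st <- stages[[si]]
    if (!is.null(st$reset_groups)) net <- reset_weights(net, st$reset_groups)
    if (!is.null(st$eps)) net$eps <- st$eps
    groups <- st$train_groups
    if (is.null(groups)) {
      groups <- names(net$weights)[net$trainable[names(net$weights)]]
    }
    smooth_z <- lapply(groups, function(g) smoothed_quantity(tau))
    names(smooth_z) <- groups
    smooth_kl <- smoothed_quantity(tau)
    state <- list(gamma0 = gamma0, kl_max = 0)
    dropout_pop <- NULL
    if (!is.null(st$dropout)) {
      lname <- st$dropout$layer
      lidx <- which(vapply(net$specs, function(s) identical(s$name, lname),
                           TRUE))
      if (length(lidx) != 1L) stop("unknown dropout layer: ", lname)
      dropout_pop <- which(net$pops$layer == lidx)
      beta <- st$dropout$beta0
    }

    for (b in seq_len(st$n_batches)) {
      idx <- sample.int(n_pat, batch_size)
      init_h <- NULL
      if (!is.null(dropout_pop)) {
        init_h <- lapply(seq_len(batch_size), function(i) {
          masks <- lapply(dropout_pop, function(p) {
            dropout_init(net$pops$n[p], beta)
          })
          setNames(masks, as.character(dropout_pop))
        })
      }
      recs <- simulate_batch(net, dataset$inputs[idx], st$spikes,
                             record_depth = net$depth, init_h = init_h)
      acc <- accumulate_gradient(recs, dataset$targets[idx], net,
                                 mode = "average", retarded = retarded)
      kl <- sum(mapply(function(i, r) {
        kl_divergence(dataset$targets[[i]], r$h[[net$output_pop]])
      }, idx, recs))
      smooth_kl <- smooth_update(smooth_kl, kl)
      lr <- learning_rate(state, smooth_kl$star)
      state <- lr$state
      for (g in groups) {
        Z <- z_transform(acc$grads[[g]], net$weights[[g]])
        smooth_z[[g]] <- smooth_update(smooth_z[[g]], Z)
        net$weights[[g]] <- optimized_update(net$weights[[g]],
                                             smooth_z[[g]]$star,
                                             lr$gamma, theta)
      }
      pred <- vapply(recs, function(r) decode_output(r$h[[net$output_pop]]),
                     1L)
      row <- data.frame(stage = if (is.null(st$name)) si else st$name,
                        batch = b, gamma = lr$gamma, kl = kl,
                        kl_star = smooth_kl$star,
                        beta = if (is.null(dropout_pop)) 1 else beta,
                        train_error = mean(pred != truth[idx]))
      log[[length(log) + 1L]] <- row
      if (!is.null(callback)) callback(net, row)
      if (!is.null(dropout_pop) && b %% st$dropout$double_every == 0L) {
        beta <- min(1, beta * 2)
      }
    }
  }
  list(net = net, log = do.call(rbind, log))
}
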