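# The SbS error-backpropagation learning rule.
#
# Training minimizes E = -sum_mu sum_q zeta(q) log h_y(q), the cross-entropy
# between the desired output zeta and the output population's latent
# variables.  The gradient with respect to a weight group decomposes into
# per-pattern (and, for shared convolutional groups, per-position)
# contributions omega built from four parts: the backward-propagated error
# Phi and the auxiliary quantities r, R and F.  Unlike standard backprop,
# Phi also travels back in time: a layer at distance m from the output is
# evaluated on latent-variable snapshots from m (Phi) and m+1 (r, R, F)
# time steps before the end of the simulation.

#' Backward error at the output layer
#'
#' `Phi(q) = (eps/(1+eps)) * zeta(q) / h_out(q)`, the seed of the backward
#' recursion, comparing the desired output distribution with the output
#' population's latent variables after the final spike.
#'
#' @param zeta Target probability vector.
#' @param h_out Output latent vector at the final time step.
#' @param eps Effective epsilon of the output population.
#' @return Non-negative vector (entries `Inf` flag a support violation).
#' @export
phi_output <- function(zeta, h_out, eps) {
  phi <- numeric(length(zeta))
  on <- zeta > 0
  phi[on] <- (eps / (1 + eps)) * zeta[on] / h_out[on]
  phi
}

#' Propagate the backward error one layer toward the input
#'
#' \deqn{\Phi_{prev}(q) = \frac{\epsilon}{1+\epsilon} \sum_{q'}
#'   \frac{\Phi_{next}(q')\,h_{next}(q')\,W(q|q')}{\sum_j h_{next}(j)W(q|j)}}
#' where `h_next` is the latent snapshot of the downstream population taken
#' one time step further in the past than the snapshot that formed
#' `phi_next`.
#'
#' @param phi_next Backward error of the downstream population.
#' @param h_next_retarded Retarded latent snapshot of that population.
#' @param W Weight matrix into the downstream population (rows: upstream
#'   neurons).
#' @param eps Effective epsilon of the downstream population.
#' @return Backward error over the upstream neurons (rows of `W`).
#' @export
phi_backstep <- function(phi_next, h_next_retarded, W, eps) {
  num <- as.vector(W %*% (h_next_retarded * phi_next))
  den <- as.vector(W %*% h_next_retarded)
  out <- numeric(nrow(W))
  pos <- den > 0
  out[pos] <- (eps / (1 + eps)) * num[pos] / den[pos]
  if (any(!pos & num > 0)) {
    stop("degenerate support in backward recursion (R(q) = 0)")
  }
  out
}

#' Auxiliary quantities r, R, F of the learning rule
#'
#' For a weight matrix `W` between an upstream and a downstream population,
#' with both latent snapshots taken from the same (retarded) time step:
#' `r(q,q') = h_post(q') W(q|q')`, `R(q) = sum_j r(q,j)` and
#' `F(q,q') = h_pre(q) h_post(q') / R(q)^2`.
#'
#' @param h_pre_retarded Upstream latent (or input) snapshot; indexes rows.
#' @param h_post_retarded Downstream latent snapshot; indexes columns.
#' @param W Weight matrix (rows: upstream neurons).
#' @return List with matrix `r`, vector `R` and matrix `F`.
#' @export
compute_rRF <- function(h_pre_retarded, h_post_retarded, W) {
  r <- sweep(W, 2L, h_post_retarded, "*")
  R <- rowSums(r)
  F_ <- outer(h_pre_retarded, h_post_retarded)
  pos <- R > 0
  F_[pos, ] <- F_[pos, , drop = FALSE] / R[pos]^2
  F_[!pos, ] <- 0
  list(r = r, R = R, F = F_)
}

#' Per-pattern gradient contribution for one weight block
#'
#' `omega(q,q') = F(q,q') * (R(q) Phi(q') - sum_j r(q,j) Phi(j))`, the
#' contribution of one pattern (and one spatial position) to the negative
#' gradient `-dE/dW`.
#'
#' @param F_ Matrix `F` from [compute_rRF()].
#' @param R Vector `R` from [compute_rRF()].
#' @param r Matrix `r` from [compute_rRF()].
#' @param phi_next Backward error of the downstream population.
#' @return Matrix of the same shape as the weight block.
#' @export
omega <- function(F_, R, r, phi_next) {
  F_ * (outer(R, phi_next) - as.vector(r %*% phi_next))
}

# snapshot of population `pop` at m steps before the end of the simulation
.snap <- function(rec, pop, m, retarded = TRUE) {
  if (!retarded) return(rec$history[[1L]][[pop]])
  rec$history[[min(m, rec$record_depth) + 1L]][[pop]]
}

# connection processing order: output-adjacent connections first, so that
# Phi at a population is complete before it acts as a downstream layer
.conn_order <- function(net) {
  order(net$pops$depth[net$conns$target])
}

# number of spatial positions (distinct target populations) per group
.group_positions <- function(net) {
  vapply(seq_along(net$weights), function(g) {
    length(unique(net$conns$target[net$conns$group == g]))
  }, 1L)
}

#' Accumulate the batch gradient of the SbS backprop rule
#'
#' Runs the backward recursion for every pattern of a simulated batch and
#' accumulates `-dE/dW` per weight group: summed over patterns, and summed
#' or averaged (default) over the spatial positions that share a
#' convolutional weight group.
#'
#' @param records List of `sbs_record`s from [simulate_batch()] (recorded
#'   to at least the network depth).
#' @param targets List of target probability vectors, one per record.
#' @param net The `sbs_network` that produced the records.
#' @param mode How contributions of weight-sharing positions combine.
#' @param retarded Use time-retarded snapshots (`TRUE`, as derived) or the
#'   final state everywhere (`FALSE`).
#' @return List with `grads` (named list of `-dE/dW` matrices for the
#'   trainable groups) and `n_patterns`.
#' @export
accumulate_gradient <- function(records, targets, net,
                                mode = c("average", "sum"),
                                retarded = TRUE) {
  mode <- match.arg(mode)
  if (length(records) != length(targets)) {
    stop("need one target per simulation record")
  }
  if (records[[1L]]$record_depth < net$depth) {
    stop("records were not taken to the network depth; re-simulate with ",
         "record_depth >= ", net$depth)
  }
  ord <- .conn_order(net)
  n_pos <- .group_positions(net)
  tr <- which(net$trainable[names(net$weights)])
  grads <- lapply(net$weights, function(W) matrix(0, nrow(W), ncol(W)))
  depth <- net$pops$depth
  out_pop <- net$output_pop
  P <- length(records)
  eps <- records[[1L]]$eps

  # snapshots of one population across the batch, as an n x P matrix
  snap_mat <- function(pop, m) {
    n <- net$pops$n[pop]
    if (!retarded) m <- 0L
    m <- min(m, records[[1L]]$record_depth)
    matrix(vapply(records, function(r) r$history[[m + 1L]][[pop]],
                  numeric(n)), nrow = n)
  }

  # backward errors per population, columns = patterns
  phi <- vector("list", nrow(net$pops))
  ZETA <- matrix(vapply(targets, identity, numeric(net$pops$n[out_pop])),
                 nrow = net$pops$n[out_pop])
  H_out <- snap_mat(out_pop, 0L)
  eps_y <- eps[out_pop]
  PHI_y <- matrix(0, nrow(ZETA), P)
  on <- ZETA > 0
  PHI_y[on] <- (eps_y / (1 + eps_y)) * ZETA[on] / H_out[on]
  phi[[out_pop]] <- PHI_y

  for (c in ord) {
    B <- net$conns$target[c]
    A <- net$conns$source[c]
    g <- net$conns$group[c]
    mB <- depth[B]
    nA <- net$pops$n[A]
    rows <- net$conns$offset[c] + seq_len(nA)
    Wr <- net$weights[[g]][rows, , drop = FALSE]
    HB <- snap_mat(B, mB + 1L)              # nB x P
    HPhi <- HB * phi[[B]]
    Rq <- Wr %*% HB                         # nA x P
    RPhi <- Wr %*% HPhi
    bad <- Rq <= 0
    if (any(bad)) {
      if (any(RPhi[bad] > 0)) {
        stop("degenerate support in backward recursion (R(q) = 0)")
      }
      Rq[bad] <- 1  # 0/0 contributions are defined as 0
      RPhi[bad] <- 0
    }
    epsB <- eps[B]
    if (!net$pops$is_input[A]) {
      contrib <- (epsB / (1 + epsB)) * RPhi / Rq
      phi[[A]] <- if (is.null(phi[[A]])) contrib else phi[[A]] + contrib
    }
    gi <- match(g, tr)
    if (!is.na(gi)) {
      HA <- snap_mat(A, mB + 1L)            # nA x P
      U <- HA / Rq
      V <- HA * RPhi / Rq^2
      # sum over patterns of outer(u_p, hphi_p) - outer(v_p, hB_p)
      om <- tcrossprod(U, HPhi) - tcrossprod(V, HB)
      scale <- if (mode == "average") n_pos[g] else 1
      grads[[g]][rows, ] <- grads[[g]][rows, ] + om / scale
    }
  }
  list(grads = grads[tr], n_patterns = P, mode = mode)
}

#' Naive reference implementation of the gradient (loop oracle)
#'
#' An independent nested-loop evaluation of the backward recursion and the
#' omega contributions for a single pattern, used to validate the
#' vectorized path on small networks.  Deliberately written element by
#' element.
#'
#' @inheritParams accumulate_gradient
#' @param record A single `sbs_record`.
#' @param target Target probability vector for the record.
#' @return List with `grads` as in [accumulate_gradient()] (single
#'   pattern).
#' @export
gradient_oracle_naive <- function(record, target, net,
                                  mode = c("average", "sum"),
                                  retarded = TRUE) {
  mode <- match.arg(mode)
  depth <- net$pops$depth
  n_pop <- nrow(net$pops)
  out_pop <- net$output_pop

  hist_of <- function(pop, m) {
    if (!retarded) m <- 0L
    record$history[[min(m, record$record_depth) + 1L]][[pop]]
  }

  # backward error, population by population, in order of distance
  phi <- vector("list", n_pop)
  eps_y <- record$eps[out_pop]
  h_y <- hist_of(out_pop, 0L)
  phi_y <- numeric(length(target))
  for (q in seq_along(target)) {
    if (target[q] > 0) {
      phi_y[q] <- (eps_y / (1 + eps_y)) * target[q] / h_y[q]
    }
  }
  phi[[out_pop]] <- phi_y

  conn_by_depth <- order(depth[net$conns$target])
  for (c in conn_by_depth) {
    B <- net$conns$target[c]; A <- net$conns$source[c]
    if (net$pops$is_input[A]) next
    W <- net$weights[[net$conns$group[c]]]
    off <- net$conns$offset[c]
    mB <- depth[B]
    hB <- hist_of(B, mB + 1L)
    epsB <- record$eps[B]
    nA <- net$pops$n[A]; nB <- net$pops$n[B]
    contrib <- numeric(nA)
    for (q in seq_len(nA)) {
      den <- 0
      for (j in seq_len(nB)) den <- den + hB[j] * W[off + q, j]
      num <- 0
      for (qp in seq_len(nB)) {
        num <- num + phi[[B]][qp] * hB[qp] * W[off + q, qp]
      }
      if (den > 0) contrib[q] <- (epsB / (1 + epsB)) * num / den
    }
    phi[[A]] <- if (is.null(phi[[A]])) contrib else phi[[A]] + contrib
  }

  # omega contributions, connection by connection
  tr <- which(net$trainable[names(net$weights)])
  grads <- lapply(net$weights[tr], function(W) matrix(0, nrow(W), ncol(W)))
  counted <- lapply(tr, function(g) character(0))
  names(counted) <- names(net$weights)[tr]
  for (c in seq_len(nrow(net$conns))) {
    g <- net$conns$group[c]
    gi <- match(g, tr)
    if (is.na(gi)) next
    B <- net$conns$target[c]; A <- net$conns$source[c]
    W <- net$weights[[g]]
    off <- net$conns$offset[c]
    mB <- depth[B]
    hB <- hist_of(B, mB + 1L)
    hA <- hist_of(A, mB + 1L)
    nA <- net$pops$n[A]; nB <- net$pops$n[B]
    for (q in seq_len(nA)) {
      Rq <- 0
      for (j in seq_len(nB)) Rq <- Rq + hB[j] * W[off + q, j]
      if (Rq <= 0) next
      for (qp in seq_len(nB)) {
        Fqqp <- hA[q] * hB[qp] / Rq^2
        acc <- 0
        for (j in seq_len(nB)) {
          r_qj <- hB[j] * W[off + q, j]
          acc <- acc + (Rq * (j == qp) - r_qj) * phi[[B]][j]
        }
        grads[[gi]][off + q, qp] <- grads[[gi]][off + q, qp] + Fqqp * acc
      }
    }
    counted[[gi]] <- union(counted[[gi]], as.character(B))
  }
  if (mode == "average") {
    for (gi in seq_along(grads)) {
      grads[[gi]] <- grads[[gi]] / length(counted[[gi]])
    }
  }
  list(grads = grads, n_patterns = 1L, mode = mode)
}

#' Normalized multiplicative weight update
#'
#' `V = W * (1 - (gamma/S) dE/dW)` with `S = max|dE/dW|` over the whole
#' weight group, so that no entry can turn negative for `gamma < 1`.  `V`
#' is floored at `theta` before column normalization, which keeps the
#' multiplicative update from locking weights at zero.  A zero gradient
#' (`S = 0`) leaves the weights unchanged.
#'
#' @param W Weight matrix.
#' @param grad Accumulated negative gradient `-dE/dW` for this group.
#' @param gamma Learning rate in (0, 1).
#' @param theta Weight floor (default 1e-4).
#' @return Updated, column-normalized weight matrix.
#' @export
multiplicative_update <- function(W, grad, gamma, theta = 1e-4) {
  S <- max(abs(grad))
  if (S == 0) return(W)
  V <- W * (1 + (gamma / S) * grad)
  normalize_columns(pmax(V, theta))
}

#' Training schedule
#'
#' A staged description of a gradient-descent training run: each stage
#' fixes the spikes per pattern and a learning-rate rule for a number of
#' learning steps.
#'
#' @param ... Stages created with [schedule_stage()].
#' @return An object of class `sbs_schedule`.
#' @export
training_schedule <- function(...) {
  structure(list(stages = list(...)), class = "sbs_schedule")
}

#' One stage of a training schedule
#'
#' @param steps Number of learning steps.
#' @param spikes Spikes per pattern used for the training simulations.
#' @param gamma Learning rate: a scalar, or a function of the 1-based step
#'   index within the stage.
#' @param name Optional stage label.
#' @return A stage description list.
#' @export
schedule_stage <- function(steps, spikes, gamma, name = NULL) {
  gfun <- if (is.function(gamma)) gamma else function(step) gamma
  list(steps = as.integer(steps), spikes = as.integer(spikes),
       gamma = gfun, name = name)
}

#' Stage-halving learning-rate rule
#'
#' The rate starts at `start` and is divided by 2 after every `every`
#' learning steps (steps `1..every-1` use `start`, `every..2*every-1` use
#' `start/2`, and so on).
#'
#' @param start Initial learning rate.
#' @param every Halving interval in learning steps.
#' @return Function of the step index.
#' @export
gamma_halving <- function(start = 0.03, every = 1000L) {
  function(step) start / 2^(step %/% every)
}

#' Train a network by batch gradient descent
#'
#' The plain training loop: per learning step, reset all latent variables,
#' simulate every pattern of the dataset for the stage's spike budget,
#' accumulate the batch gradient and apply the normalized multiplicative
#' update to every trainable weight group.  Logs the output cross-entropy
#' and the training classification error (decoded from the training
#' simulations) per step.
#'
#' @param net An `sbs_network`.
#' @param dataset A `pattern_set`.
#' @param schedule An [training_schedule()].
#' @param mode Position-combining mode for shared groups (see
#'   [accumulate_gradient()]).
#' @param retarded Use time-retarded snapshots in the learning rule.
#' @param theta Weight floor of the multiplicative update.
#' @param callback Optional `function(net, log_row)` called after every
#'   step (e.g. for interleaved evaluation).
#' @return List with the trained `net` and a data-frame `log` (stage,
#'   step, gamma, spikes, objective, train_error).
#' @export
train_simple <- function(net, dataset, schedule, mode = "average",
                         retarded = TRUE, theta = 1e-4, callback = NULL) {
  stopifnot(inherits(schedule, "sbs_schedule"))
  log <- list()
  truth <- vapply(dataset$targets, which.max, 1L)
  tr_groups <- names(net$weights)[net$trainable[names(net$weights)]]
  for (si in seq_along(schedule$stages)) {
    st <- schedule$stages[[si]]
    for (step in seq_len(st$steps)) {
      gam <- st$gamma(step)
      recs <- simulate_batch(net, dataset$inputs, st$spikes,
                             record_depth = net$depth)
      acc <- accumulate_gradient(recs, dataset$targets, net, mode = mode,
                                 retarded = retarded)
      h_out <- lapply(recs, function(r) r$h[[net$output_pop]])
      obj <- sum(mapply(function(z, h) cross_entropy(z, h),
                        dataset$targets, h_out))
      pred <- vapply(h_out, decode_output, 1L)
      if (gam > 0) {
        for (g in tr_groups) {
          net$weights[[g]] <- multiplicative_update(
            net$weights[[g]], acc$grads[[g]], gam, theta)
        }
      }
      row <- data.frame(stage = if (is.null(st$name)) si else st$name,
                        step = step, gamma = gam, spikes = st$spikes,
                        objective = obj,
                        train_error = mean(pred != truth))
      log[[length(log) + 1L]] <- row
      if (!is.null(callback)) callback(net, row)
    }
  }
  list(net = net, log = do.call(rbind, log))
}
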