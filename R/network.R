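# Feed-forward SbS architectures built from a single population primitive.
#
# A network is stored in flattened form: a population table (input modules
# first, then inference populations layer by layer, row-major within each
# layer's grid) and a connection table.  Each connection carries the index
# of its weight group and a row offset, so a population with several
# afferents reads from disjoint row blocks of one composite weight matrix.

#' Epsilon configuration for a simulation
#'
#' The smoothing parameter of the h-dynamic.  Each population uses
#' `base / divisor`, where the per-layer divisor compensates for the number
#' of spikes a population receives per time step.  Optionally, after
#' `breakpoint` time steps `base` is divided by `post_divisor`, reducing
#' latent-variable fluctuations so that the remaining spikes implement an
#' implicit temporal average.
#'
#' @param base Base smoothing parameter (epsilon_0), > 0.
#' @param divisor Per-layer divisor (positive), usually the fan-in.
#' @param breakpoint Time step after which the reduced epsilon applies;
#'   `Inf` disables the schedule.
#' @param post_divisor Factor by which `base` shrinks after the breakpoint.
#' @return An object of class `epsilon_setting`.
#' @export
epsilon_setting <- function(base = 0.1, divisor = 1L, breakpoint = Inf,
                            post_divisor = 25) {
  stopifnot(base > 0, divisor >= 1, post_divisor > 0)
  structure(list(base = base, divisor = divisor, breakpoint = breakpoint,
                 post_divisor = post_divisor),
            class = "epsilon_setting")
}

#' Effective epsilon at a given point of a simulation
#'
#' @param setting An [epsilon_setting()].
#' @param spikes_processed Number of spikes (time steps) the population has
#'   processed so far.
#' @return Positive scalar epsilon.
#' @export
effective_epsilon <- function(setting, spikes_processed = 0) {
  base <- setting$base
  if (is.finite(setting$breakpoint) && spikes_processed >= setting$breakpoint) {
    base <- base / setting$post_divisor
  }
  base / setting$divisor
}

#' Describe one layer of a feed-forward SbS network
#'
#' @param kind One of `"input"`, `"dense"`, `"conv"`, `"pool"`, `"output"`.
#' @param neurons Neurons per population in this layer.
#' @param grid `(rows, cols)` of populations; input layers give the module
#'   grid here, `dense`/`output` layers are a single population.
#' @param kernel `(kh, kw)` receptive field for `conv`/`pool` layers.
#' @param stride `(sh, sw)`; defaults to 1 for `conv` and to `kernel` for
#'   `pool`.
#' @param eps_divisor Per-layer epsilon divisor (see [epsilon_setting()]).
#' @param weight_group Optional name for the afferent weight group; layers
#'   naming the same group share one matrix.
#' @param trainable Whether the afferent weights are learned; pooling
#'   weights are always fixed.
#' @param name Optional layer name.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind = c("input", "dense", "conv", "pool", "output"),
                       neurons, grid = c(1L, 1L), kernel = NULL,
                       stride = NULL, eps_divisor = 1, weight_group = NULL,
                       trainable = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("conv", "pool")) {
    if (is.null(kernel)) stop(kind, " layer needs a kernel")
    if (is.null(stride)) stride <- if (kind == "pool") kernel else c(1L, 1L)
  }
  if (kind == "pool") trainable <- FALSE
  if (is.null(trainable)) trainable <- kind != "input"
  structure(list(kind = kind, neurons = as.integer(neurons),
                 grid = as.integer(grid), kernel = kernel, stride = stride,
                 eps_divisor = eps_divisor, weight_group = weight_group,
                 trainable = trainable, name = name),
            class = "layer_spec")
}

#' Fixed weights of a competition-based pooling population
#'
#' Pooling is realized by the same population primitive as every other
#' layer: a pooling population receives the spikes of a spatial patch of
#' feature populations through a fixed, feature-block weight matrix in
#' which inputs from different features do not mix.  The spatial copies of
#' each feature then compete through the ordinary h-dynamic, so features
#' with strong input dominate the pooled representation.
#'
#' @param n_features Number of features (neurons per population).
#' @param patch_area Number of afferent populations (e.g. 4 for 2x2).
#' @return A `(patch_area * n_features) x n_features` weight matrix with
#'   entries `1/patch_area` on the feature-diagonal blocks.
#' @export
build_pooling_weights <- function(n_features, patch_area) {
  stopifnot(n_features >= 1, patch_area >= 1)
  W <- matrix(0, nrow = patch_area * n_features, ncol = n_features)
  for (k in seq_len(patch_area)) {
    idx <- (k - 1L) * n_features + seq_len(n_features)
    W[cbind(idx, seq_len(n_features))] <- 1 / patch_area
  }
  W
}

#' Random initialization of a weight matrix
#'
#' `V = 1 + scale * U[0,1]` elementwise, then column-normalized, so all
#' entries start near `1/n_in` with small random asymmetries that the
#' competition within populations can amplify.
#'
#' @param n_in Number of rows (afferent input neurons).
#' @param n_out Number of columns (population neurons).
#' @param scale Amplitude of the uniform perturbation (default 0.01).
#' @return Column-normalized weight matrix.
#' @export
init_weights_random <- function(n_in, n_out, scale = 0.01) {
  V <- 1 + scale * matrix(runif(n_in * n_out), n_in, n_out)
  normalize_columns(V)
}

#' Build a feed-forward SbS network from layer specifications
#'
#' Computes the population grid of every layer from kernel/stride geometry
#' ("valid" windows, no padding), derives the afferent list of every
#' population, instantiates one weight matrix per weight-sharing group
#' (random for trainable groups, the fixed feature-block matrix for pooling
#' layers), and assigns each layer its distance from the output layer,
#' which the time-retarded learning rule uses to pick latent-variable
#' snapshots.
#'
#' @param specs List of [layer_spec()]s, first `input`, last `output`.
#' @param eps An [epsilon_setting()] giving `base`, `breakpoint` and
#'   `post_divisor`; per-layer divisors come from the specs.
#' @param init_scale Scale of the random weight initialization.
#' @return An object of class `sbs_network`.
#' @export
build_feedforward <- function(specs, eps = epsilon_setting(),
                              init_scale = 0.01) {
  L <- length(specs)
  stopifnot(L >= 2, specs[[1L]]$kind == "input",
            specs[[L]]$kind == "output")

  grids <- vector("list", L)
  for (l in seq_len(L)) {
    sp <- specs[[l]]
    grids[[l]] <- switch(sp$kind,
      input = sp$grid,
      dense = ,
      output = c(1L, 1L),
      conv = ,
      pool = {
        gin <- grids[[l - 1L]]
        k <- sp$kernel; s <- sp$stride
        if (any(k > gin)) stop("kernel larger than input grid in layer ", l)
        out <- (gin - k) %/% s + 1L
        if (any(out < 1L)) stop("empty output grid in layer ", l)
        as.integer(out)
      })
    if (is.null(sp$name)) specs[[l]]$name <- paste0(sp$kind, l - 1L)
  }

  # population table
  pop_layer <- integer(0); pop_n <- integer(0); pop_row <- integer(0)
  pop_col <- integer(0)
  first_pop <- integer(L)  # index of first population of each layer
  for (l in seq_len(L)) {
    g <- grids[[l]]
    first_pop[l] <- length(pop_layer) + 1L
    for (r in seq_len(g[1L])) for (cc in seq_len(g[2L])) {
      pop_layer <- c(pop_layer, l)
      pop_n <- c(pop_n, specs[[l]]$neurons)
      pop_row <- c(pop_row, r); pop_col <- c(pop_col, cc)
    }
  }
  n_pop <- length(pop_layer)
  pop_depth <- L - pop_layer          # distance from the output layer
  pop_is_input <- pop_layer == 1L
  pop_emits <- pop_layer < L          # output layer emits no spikes

  pop_at <- function(l, r, cc) {
    first_pop[l] + (r - 1L) * grids[[l]][2L] + (cc - 1L)
  }

  # connections and weight groups
  weights <- list(); trainable <- logical(0)
  conn <- list(target = integer(0), source = integer(0),
               group = integer(0), offset = integer(0))
  group_id <- function(name, nrow_, ncol_, sp) {
    if (!name %in% names(weights)) {
      W <- if (sp$kind == "pool") {
        build_pooling_weights(sp$neurons, nrow_ %/% sp$neurons)
      } else {
        init_weights_random(nrow_, ncol_, init_scale)
      }
      weights[[name]] <<- W
      trainable[name] <<- isTRUE(sp$trainable)
    } else if (!all(dim(weights[[name]]) == c(nrow_, ncol_))) {
      stop("weight group '", name, "' reused with mismatching shape")
    }
    match(name, names(weights))
  }

  for (l in 2L:L) {
    sp <- specs[[l]]
    gin <- grids[[l - 1L]]; gout <- grids[[l]]
    n_src <- specs[[l - 1L]]$neurons
    gname <- if (!is.null(sp$weight_group)) sp$weight_group else
      paste0("W_", specs[[l - 1L]]$name, "_", sp$name)
    if (sp$kind %in% c("dense", "output")) {
      sources <- first_pop[l - 1L] + seq_len(prod(gin)) - 1L
      g <- group_id(gname, length(sources) * n_src, sp$neurons, sp)
      for (k in seq_along(sources)) {
        conn$target <- c(conn$target, pop_at(l, 1L, 1L))
        conn$source <- c(conn$source, sources[k])
        conn$group <- c(conn$group, g)
        conn$offset <- c(conn$offset, (k - 1L) * n_src)
      }
    } else {  # conv / pool: one shared weight group for all positions
      if (sp$kind == "pool" && n_src != sp$neurons) {
        stop("pooling layer must keep the feature count of its input")
      }
      k <- sp$kernel; s <- sp$stride
      g <- group_id(gname, prod(k) * n_src, sp$neurons, sp)
      for (r in seq_len(gout[1L])) for (cc in seq_len(gout[2L])) {
        tgt <- pop_at(l, r, cc)
        idx <- 0L
        for (dr in seq_len(k[1L])) for (dc in seq_len(k[2L])) {
          src <- pop_at(l - 1L, (r - 1L) * s[1L] + dr,
                        (cc - 1L) * s[2L] + dc)
          conn$target <- c(conn$target, tgt)
          conn$source <- c(conn$source, src)
          conn$group <- c(conn$group, g)
          conn$offset <- c(conn$offset, idx * n_src)
          idx <- idx + 1L
        }
      }
    }
  }

  ord <- order(conn$target, seq_along(conn$target))  # row-major afferents
  conns <- data.frame(target = conn$target[ord], source = conn$source[ord],
                      group = conn$group[ord], offset = conn$offset[ord])

  pops <- data.frame(
    layer = pop_layer, n = pop_n, depth = pop_depth, row = pop_row,
    col = pop_col, is_input = pop_is_input, emits = pop_emits,
    eps_divisor = vapply(pop_layer, function(l) specs[[l]]$eps_divisor, 1))
  multi <- tabulate(pop_layer)[pop_layer] > 1L
  pops$name <- paste0(vapply(pop_layer, function(l) specs[[l]]$name, ""),
                      ifelse(multi, paste0("[", pop_row, ",", pop_col, "]"),
                             ""))

  structure(list(specs = specs, grids = grids, pops = pops, conns = conns,
                 weights = weights, trainable = trainable, eps = eps,
                 depth = max(pop_depth), n_input = sum(pop_is_input),
                 input_pops = which(pop_is_input),
                 output_pop = n_pop),
            class = "sbs_network")
}

#' @export
print.sbs_network <- function(x, ...) {
  cat("Feed-forward SbS network:", length(x$specs), "layers,",
      nrow(x$pops), "populations,", sum(x$pops$n), "neurons\n")
  for (l in seq_along(x$specs)) {
    sp <- x$specs[[l]]
    g <- x$grids[[l]]
    cat(sprintf("  %-8s %-6s grid %dx%d, %d neurons/pop, eps/%g\n",
                sp$name, sp$kind, g[1L], g[2L], sp$neurons, sp$eps_divisor))
  }
  cat("Weight groups:",
      paste0(names(x$weights), ifelse(x$trainable, "", " (fixed)"),
             collapse = ", "), "\n")
  invisible(x)
}

#' Reset latent variables to the uniform distribution
#'
#' Before every pattern presentation each population's latent variables
#' start at `1/N` (dropout initialization can override this, see
#' [dropout_init()]).
#'
#' @param net An `sbs_network`.
#' @return Named list of uniform latent vectors, one per population
#'   (`NULL` for input modules).
#' @export
reset_latent <- function(net) {
  h <- vector("list", nrow(net$pops))
  for (p in seq_len(nrow(net$pops))) {
    if (!net$pops$is_input[p]) h[[p]] <- rep(1 / net$pops$n[p], net$pops$n[p])
  }
  h
}

#' Re-randomize selected weight groups
#'
#' Used by staged training protocols that reset the upper layers to random
#' values between stages.  Pooling (fixed) groups cannot be reset.
#'
#' @param net An `sbs_network`.
#' @param groups Character vector of weight-group names.
#' @param init_scale Scale of the random initialization.
#' @return The network with fresh weights in the named groups.
#' @export
reset_weights <- function(net, groups, init_scale = 0.01) {
  for (g in groups) {
    if (!g %in% names(net$weights)) stop("unknown weight group: ", g)
    if (!net$trainable[[g]]) stop("cannot reset fixed group: ", g)
    d <- dim(net$weights[[g]])
    net$weights[[g]] <- init_weights_random(d[1L], d[2L], init_scale)
  }
  net
}

# Per-population effective epsilons (before/after the breakpoint).
.pop_epsilons <- function(net) {
  pre <- net$eps$base / net$pops$eps_divisor
  post <- (net$eps$base / net$eps$post_divisor) / net$pops$eps_divisor
  bp <- if (is.finite(net$eps$breakpoint)) as.integer(net$eps$breakpoint)
        else -1L
  list(pre = pre, post = post, breakpoint = bp)
}

#' Simulate a batch of patterns spike by spike
#'
#' Per time step, every input module and every non-output population draws
#' one spike from its distribution as it stood at the start of the step
#' (synchronous scheme); every population then applies the h-dynamic once
#' per afferent spike, in a fixed row-major afferent order.  The trailing
#' `record_depth + 1` latent-variable snapshots are recorded for the
#' time-retarded learning rule.
#'
#' @param net An `sbs_network`.
#' @param inputs List of patterns; each pattern is a list with one
#'   probability vector per input module (row-major module order).
#' @param n_steps Number of time steps, i.e. spikes per emitting
#'   population.
#' @param record_depth How many past snapshots to keep (defaults to the
#'   network depth; 0 records only the final state).
#' @param init_h Optional per-pattern latent initialization: a list (one
#'   element per pattern) of named lists mapping population index to an
#'   initial latent vector (used for dropout).
#' @return List of `sbs_record` objects with elements `h` (final latent
#'   vectors per population), `history` (snapshots `t, t-1, ...`),
#'   `spikes_emitted`, `skipped`, `n_steps` and `eps` (effective epsilon
#'   per population at the final step).
#' @export
simulate_batch <- function(net, inputs, n_steps,
                           record_depth = net$depth, init_h = NULL) {
  n_pop <- nrow(net$pops)
  uniform <- reset_latent(net)
  h0 <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    pat <- inputs[[i]]
    if (length(pat) != net$n_input) {
      stop("pattern ", i, " has ", length(pat), " input distributions, ",
           "network expects ", net$n_input)
    }
    hp <- uniform
    for (k in seq_len(net$n_input)) {
      p <- pat[[k]]
      pop <- net$input_pops[k]
      if (length(p) != net$pops$n[pop]) {
        stop("input distribution ", k, " has wrong length")
      }
      hp[[pop]] <- p
    }
    if (!is.null(init_h) && !is.null(init_h[[i]])) {
      ov <- init_h[[i]]
      for (nm in names(ov)) hp[[as.integer(nm)]] <- ov[[nm]]
    }
    h0[[i]] <- hp
  }

  e <- .pop_epsilons(net)
  raw <- sbs_simulate_batch_cpp(
    pop_n = net$pops$n,
    pop_is_input = net$pops$is_input,
    pop_emits = net$pops$emits,
    pop_eps_pre = e$pre, pop_eps_post = e$post,
    eps_breakpoint = e$breakpoint,
    conn_target = net$conns$target - 1L,
    conn_source = net$conns$source - 1L,
    conn_group = net$conns$group - 1L,
    conn_offset = net$conns$offset,
    weights = unname(net$weights),
    h0 = h0, n_steps = as.integer(n_steps),
    record_depth = as.integer(record_depth))

  post <- e$breakpoint > 0 && n_steps > e$breakpoint
  eps_final <- if (post) e$post else e$pre
  lapply(raw, function(r) {
    r$eps <- eps_final
    r$record_depth <- record_depth
    class(r) <- "sbs_record"
    r
  })
}

#' Simulate a single pattern
#'
#' Convenience wrapper around [simulate_batch()] for one pattern.
#'
#' @inheritParams simulate_batch
#' @param input List with one probability vector per input module.
#' @return An `sbs_record`.
#' @export
simulate_pattern <- function(net, input, n_steps,
                             record_depth = net$depth, init_h = NULL) {
  simulate_batch(net, list(input), n_steps, record_depth,
                 init_h = if (is.null(init_h)) NULL else list(init_h))[[1L]]
}

#' Decode the class from the output population
#'
#' The output neuron with the highest latent variable wins; ties break
#' toward the lowest index.
#'
#' @param h_out Latent vector of the output population.
#' @return 1-based class index.
#' @export
decode_output <- function(h_out) which.max(h_out)

#' Evaluate classification performance
#'
#' Simulates every pattern with a fresh (uniform) latent state and a given
#' spike budget, decodes the output population by argmax, and compares with
#' the target class.
#'
#' @param net An `sbs_network`.
#' @param dataset A `pattern_set` (see [make_xor_dataset()]).
#' @param spikes Spikes per pattern used for evaluation (default 1024).
#' @return List with `error` (fraction misclassified), `predicted` and
#'   `truth` (1-based class indices).
#' @export
evaluate_network <- function(net, dataset, spikes = 1024L) {
  recs <- simulate_batch(net, dataset$inputs, spikes, record_depth = 0L)
  pred <- vapply(recs, function(r) decode_output(r$h[[net$output_pop]]), 1L)
  truth <- vapply(dataset$targets, which.max, 1L)
  list(error = mean(pred != truth), predicted = pred, truth = truth)
}
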