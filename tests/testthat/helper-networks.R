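# Shared generators for property-style tests: random probability vectors,
# random weight matrices, and small random networks with matching datasets.

random_prob <- function(n) {
  p <- runif(n)
  p / sum(p)
}

random_weights <- function(n_in, n_out) {
  normalize_columns(matrix(runif(n_in * n_out) + 0.05, n_in, n_out))
}

# a dense chain network with random layer sizes, plus one random pattern
# per requested count
random_micro_network <- function(n_hidden = sample(1:3, 1),
                                 max_neurons = 6L) {
  sizes <- sample(2:max_neurons, n_hidden + 2L, replace = TRUE)
  specs <- list(layer_spec("input", neurons = sizes[1L], name = "X"))
  for (i in seq_len(n_hidden)) {
    specs[[i + 1L]] <- layer_spec("dense", neurons = sizes[i + 1L],
                                  name = paste0("H", i))
  }
  specs[[n_hidden + 2L]] <- layer_spec("output",
                                       neurons = sizes[n_hidden + 2L],
                                       name = "HY")
  build_feedforward(specs)
}

# a micro network with a weight-sharing layer (1x2 grid, 1x1 kernel), the
# smallest case exercising per-position gradient combination
random_shared_network <- function(max_neurons = 6L) {
  n_in <- sample(2:max_neurons, 1L)
  n_h <- sample(2:max_neurons, 1L)
  n_mid <- sample(2:max_neurons, 1L)
  n_out <- sample(2:3, 1L)
  build_feedforward(list(
    layer_spec("input", neurons = n_in, grid = c(1L, 2L), name = "X"),
    layer_spec("conv", neurons = n_h, kernel = c(1L, 1L),
               stride = c(1L, 1L), name = "H1"),
    layer_spec("dense", neurons = n_mid, name = "H2"),
    layer_spec("output", neurons = n_out, name = "HY")))
}

random_dataset_for <- function(net, n_patterns = 2L) {
  n_out <- net$pops$n[net$output_pop]
  inputs <- lapply(seq_len(n_patterns), function(i) {
    lapply(net$input_pops, function(p) random_prob(net$pops$n[p]))
  })
  targets <- lapply(seq_len(n_patterns), function(i) {
    z <- numeric(n_out)
    z[sample.int(n_out, 1L)] <- 1
    z
  })
  pattern_set(inputs, targets)
}
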