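# Benchmark tasks and their network topologies.
#
# Boolean inputs are encoded by two-neuron groups (first neuron active for
# bit value 0, second for bit value 1); a pattern's input distribution
# spreads its mass equally over the active neurons, and is exact rather
# than sampled -- stochasticity enters only through the spike draws of the
# simulation.

#' Construct a pattern set
#'
#' @param inputs List of patterns, each a list of probability vectors (one
#'   per input module).
#' @param targets List of target probability vectors over output neurons.
#' @param names Optional pattern labels.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(inputs, targets, names = NULL) {
  stopifnot(length(inputs) == length(targets))
  for (pat in inputs) lapply(pat, check_prob_vector)
  lapply(targets, check_prob_vector)
  structure(list(inputs = inputs, targets = targets, names = names),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set:", length(x$inputs), "patterns,",
      length(x$inputs[[1L]]), "input module(s),",
      length(x$targets[[1L]]), "classes\n")
  invisible(x)
}

# two-neuron encoding of a bit vector: mass 1/length(bits) on the active
# neuron of each two-neuron group
.encode_bits <- function(bits) {
  p <- numeric(2L * length(bits))
  for (i in seq_along(bits)) p[2L * (i - 1L) + 1L + bits[i]] <- 1
  p / sum(p)
}

.one_hot <- function(class, n) { z <- numeric(n); z[class] <- 1; z }

#' The XOR task
#'
#' Four patterns of two bits; one input module of four neurons (two
#' two-neuron bit groups, the two active neurons at 0.5 each); target class
#' 1 for equal bits, class 2 for unequal bits.
#'
#' @return A `pattern_set`.
#' @export
make_xor_dataset <- function() {
  pats <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  inputs <- list(); targets <- list(); nm <- character(0)
  for (i in seq_len(nrow(pats))) {
    b <- pats[i, ]
    inputs[[i]] <- list(.encode_bits(b))
    targets[[i]] <- .one_hot(1L + (sum(b) %% 2L), 2L)
    nm[i] <- paste0(b, collapse = "")
  }
  pattern_set(inputs, targets, nm)
}

#' The 4-bit parity task
#'
#' Sixteen patterns of four bits; the target class is 1 for an even number
#' of ones and 2 for an odd number.  Unsplit: one input module of eight
#' neurons (four active at 0.25).  Split: two modules `Xa` (bits 1-2) and
#' `Xb` (bits 3-4) of four neurons each (two active at 0.5).
#'
#' @param split Use the split input encoding.
#' @return A `pattern_set`.
#' @export
make_parity_dataset <- function(split = FALSE) {
  inputs <- list(); targets <- list(); nm <- character(0)
  i <- 0L
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) for (b4 in 0:1) {
    i <- i + 1L
    b <- c(b1, b2, b3, b4)
    inputs[[i]] <- if (split) {
      list(.encode_bits(b[1:2]), .encode_bits(b[3:4]))
    } else {
      list(.encode_bits(b))
    }
    targets[[i]] <- .one_hot(1L + (sum(b) %% 2L), 2L)
    nm[i] <- paste0(b, collapse = "")
  }
  pattern_set(inputs, targets, nm)
}

#' XOR network topology
#'
#' One input module of 4 neurons, a hidden population of 4 and an output
#' population of 2, with epsilon = 0.1 throughout.
#'
#' @param eps0 Base epsilon.
#' @param init_scale Scale of the random weight initialization.
#' @return An `sbs_network`.
#' @export
build_xor_network <- function(eps0 = 0.1, init_scale = 0.01) {
  build_feedforward(list(
    layer_spec("input", neurons = 4L, name = "X"),
    layer_spec("dense", neurons = 4L, name = "H1"),
    layer_spec("output", neurons = 2L, name = "HY")),
    eps = epsilon_setting(base = eps0), init_scale = init_scale)
}

#' 4-bit parity network topology
#'
#' Unsplit: input 8 -> hidden 8 -> hidden 4 -> output 2 (three emitting
#' populations per time step).  Split: the first hidden layer is divided
#' into two populations `H1a`/`H1b` of 4 neurons that see only their half
#' of the input and share one weight matrix (five emitting populations per
#' time step); their two gradient contributions are averaged.
#'
#' @param split Build the split-H1 variant.
#' @param eps0 Base epsilon.
#' @param init_scale Scale of the random weight initialization.
#' @return An `sbs_network`.
#' @export
build_parity_network <- function(split = FALSE, eps0 = 0.1,
                                 init_scale = 0.01) {
  if (split) {
    build_feedforward(list(
      layer_spec("input", neurons = 4L, grid = c(1L, 2L), name = "X"),
      layer_spec("conv", neurons = 4L, kernel = c(1L, 1L),
                 stride = c(1L, 1L), name = "H1", weight_group = "W_X_H1"),
      layer_spec("dense", neurons = 4L, name = "H2"),
      layer_spec("output", neurons = 2L, name = "HY")),
      eps = epsilon_setting(base = eps0), init_scale = init_scale)
  } else {
    build_feedforward(list(
      layer_spec("input", neurons = 8L, name = "X"),
      layer_spec("dense", neurons = 8L, name = "H1"),
      layer_spec("dense", neurons = 4L, name = "H2"),
      layer_spec("output", neurons = 2L, name = "HY")),
      eps = epsilon_setting(base = eps0), init_scale = init_scale)
  }
}

#' Hand-crafted ideal XOR weights
#'
#' The exemplary solution: each hidden neuron represents one bit pattern
#' (00, 01, 10, 11) with weight 0.5 from each of its two active input
#' neurons; the output weights route 00/11 to class 1 and 01/10 to class 2
#' with weight 0.5 each.
#'
#' @param net An XOR network from [build_xor_network()].
#' @return The network with the ideal weights installed.
#' @export
ideal_xor_weights <- function(net) {
  W1 <- matrix(0, 4L, 4L)  # rows: input neurons (b1=0,b1=1,b2=0,b2=1)
  pats <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (j in seq_along(pats)) {
    b <- pats[[j]]
    W1[1L + b[1L], j] <- 0.5
    W1[3L + b[2L], j] <- 0.5
  }
  W2 <- matrix(0, 4L, 2L)  # rows: hidden neurons 00,01,10,11
  W2[c(1L, 4L), 1L] <- 0.5  # equal bits -> class 1
  W2[c(2L, 3L), 2L] <- 0.5  # unequal bits -> class 2
  net$weights[[1L]] <- W1
  net$weights[[2L]] <- W2
  net
}

#' Synthetic bar-image task for convolutional architectures
#'
#' Desk-scale stand-in for image classification: binary images containing a
#' single full-length horizontal (class 1) or vertical (class 2) bar at a
#' random position, with optional pixel-flip noise, on/off encoded pixel by
#' pixel into two-neuron input modules.  Synthetic by construction.
#'
#' @param n_per_class Patterns per class.
#' @param size Image side length in pixels.
#' @param noise Per-pixel flip probability.
#' @return A `pattern_set`; the raw images are attached as attribute
#'   `images`.
#' @export
make_toy_conv_task <- function(n_per_class = 10L, size = 8L, noise = 0) {
  inputs <- list(); targets <- list(); nm <- character(0); imgs <- list()
  k <- 0L
  for (cls in 1:2) for (i in seq_len(n_per_class)) {
    k <- k + 1L
    img <- matrix(0, size, size)
    pos <- sample.int(size, 1L)
    if (cls == 1L) img[pos, ] <- 1 else img[, pos] <- 1
    if (noise > 0) {
      flip <- matrix(runif(size * size) < noise, size, size)
      img[flip] <- 1 - img[flip]
    }
    ch <- on_off_encode(as.vector(t(img)))  # row-major pixel order
    inputs[[k]] <- lapply(seq_len(size * size),
                          function(px) as.numeric(ch[px, ]))
    targets[[k]] <- .one_hot(cls, 2L)
    nm[k] <- paste0(c("h", "v")[cls], pos)
    imgs[[k]] <- img
  }
  ps <- pattern_set(inputs, targets, nm)
  attr(ps, "images") <- imgs
  ps
}

#' Small convolutional network for the bar task
#'
#' On/off input grid -> shared-weight convolutional layer -> output, with
#' the output epsilon divided by its fan-in.
#'
#' @param size Image side length.
#' @param kernel Convolution kernel side length.
#' @param n_filters Neurons per convolutional population.
#' @param n_classes Output classes.
#' @param eps0 Base epsilon.
#' @return An `sbs_network`.
#' @export
build_toy_conv_network <- function(size = 8L, kernel = 5L, n_filters = 8L,
                                   n_classes = 2L, eps0 = 0.1) {
  n_pos <- (size - kernel + 1L)^2
  build_feedforward(list(
    layer_spec("input", neurons = 2L, grid = c(size, size), name = "X"),
    layer_spec("conv", neurons = n_filters, kernel = c(kernel, kernel),
               stride = c(1L, 1L), name = "H1"),
    layer_spec("output", neurons = n_classes, eps_divisor = n_pos,
               name = "HY")),
    eps = epsilon_setting(base = eps0))
}

#' Deep convolutional architecture for 28x28 images
#'
#' The full digit-classification architecture: on/off input 28x28 (x2
#' neurons) -> 5x5 convolution with 32 filters (24x24) -> 2x2 pooling
#' (12x12) -> 5x5 convolution with 64 filters (8x8) -> 2x2 pooling (4x4)
#' -> fully connected population of 1024 -> output of 10.  Pooling weights
#' are fixed feature-block matrices; per-layer epsilon divisors follow the
#' fan-in-compensation table (1, 4, 25, 4, 16, 1), and after
#' `eps_breakpoint` time steps the base epsilon drops by a factor 25.
#'
#' @param eps0 Base epsilon.
#' @param eps_breakpoint Time step of the epsilon schedule (default 1000).
#' @return An `sbs_network`.
#' @export
build_deep_conv_network <- function(eps0 = 0.1, eps_breakpoint = 1000L) {
  build_feedforward(list(
    layer_spec("input", neurons = 2L, grid = c(28L, 28L), name = "X"),
    layer_spec("conv", neurons = 32L, kernel = c(5L, 5L),
               stride = c(1L, 1L), eps_divisor = 1, name = "H1"),
    layer_spec("pool", neurons = 32L, kernel = c(2L, 2L), eps_divisor = 4,
               name = "H2"),
    layer_spec("conv", neurons = 64L, kernel = c(5L, 5L),
               stride = c(1L, 1L), eps_divisor = 25, name = "H3"),
    layer_spec("pool", neurons = 64L, kernel = c(2L, 2L), eps_divisor = 4,
               name = "H4"),
    layer_spec("dense", neurons = 1024L, eps_divisor = 16, name = "H5"),
    layer_spec("output", neurons = 10L, eps_divisor = 1, name = "HY")),
    eps = epsilon_setting(base = eps0, breakpoint = eps_breakpoint,
                          post_divisor = 25))
}

#' Convert images and labels to a pattern set
#'
#' On/off encodes each pixel of a stack of grayscale images into two-neuron
#' input modules (row-major pixel order) and one-hot encodes the labels.
#'
#' @param images 3-d array `(n, rows, cols)` with intensities in \[0, 1\].
#' @param labels Integer labels `0 .. n_classes-1`.
#' @param n_classes Number of classes.
#' @return A `pattern_set`.
#' @export
images_to_pattern_set <- function(images, labels, n_classes = 10L) {
  stopifnot(length(dim(images)) == 3L, dim(images)[1L] == length(labels))
  n <- dim(images)[1L]
  inputs <- vector("list", n); targets <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- on_off_encode(as.vector(t(images[i, , ])))
    inputs[[i]] <- lapply(seq_len(nrow(ch)),
                          function(px) as.numeric(ch[px, ]))
    targets[[i]] <- .one_hot(labels[i] + 1L, n_classes)
  }
  pattern_set(inputs, targets)
}
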