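#' @useDynLib sbsnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
NULL

.TOL_NORM <- 1e-12

#' Validate a probability vector
#'
#' A probability vector holds the input distribution `p(s)`, the latent
#' variables `h(i)` of an inference population, or a classification target
#' `zeta(q)`: all elements non-negative and summing to one.  An all-zero
#' vector is allowed but flagged degenerate (it may not be sampled from).
#'
#' @param p Numeric vector.
#' @param tol Tolerance on the deviation of `sum(p)` from 1.
#' @return `p` invisibly; errors if invalid.
#' @export
check_prob_vector <- function(p, tol = .TOL_NORM) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("probability vector must be a non-empty numeric vector")
  }
  if (any(p < 0)) stop("probability vector has negative elements")
  s <- sum(p)
  if (s == 0) return(invisible(p))  # degenerate, but valid as a non-emitter
  if (abs(s - 1) > tol) {
    stop(sprintf("probability vector sums to %.15g, not 1", s))
  }
  invisible(p)
}

#' Is a probability vector degenerate (all-zero)?
#' @param p Numeric vector.
#' @return Logical scalar.
#' @export
is_degenerate <- function(p) sum(p) <= 0

#' Column-normalize a non-negative matrix
#'
#' Weight matrices `W(s|i)` between populations are non-negative with each
#' column summing to one over the afferent input neurons `s`; this enforces
#' that convention, preserving within-column proportions.
#'
#' @param V Non-negative numeric matrix (rows: input neurons, columns:
#'   population neurons).
#' @return Matrix with unit column sums.
#' @export
normalize_columns <- function(V) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("weight matrix entries must be non-negative")
  cs <- colSums(V)
  if (any(cs <= 0)) stop("degenerate column: column sum must be positive")
  sweep(V, 2L, cs, "/")
}

#' Validate a weight matrix
#' @param W Numeric matrix.
#' @param tol Tolerance on column sums.
#' @return `W` invisibly; errors if invalid.
#' @export
check_weight_matrix <- function(W, tol = .TOL_NORM) {
  if (any(W < 0)) stop("weight matrix has negative entries")
  if (any(abs(colSums(W) - 1) > tol)) {
    stop("weight matrix columns must sum to 1")
  }
  invisible(W)
}

#' Draw one spike from a probability distribution
#'
#' A population emits exactly one spike per time step: a single categorical
#' draw of the index of the next firing neuron (the Bernoulli-process view
#' of the input).  Uses R's global RNG via inverse-CDF sampling so that the
#' draw sequence matches the C++ simulation kernel under the same seed.
#'
#' @param p Probability vector.
#' @return 1-based neuron index, or `NA_integer_` when `p` is degenerate
#'   (no spike this step).
#' @export
draw_spike <- function(p) {
  tot <- sum(p)
  if (tot <= 0) return(NA_integer_)
  u <- runif(1L) * tot
  idx <- which(cumsum(p) >= u)
  if (length(idx) == 0L) max(which(p > 0)) else idx[1L]
}

#' Per-spike multiplicative update of latent variables (h-dynamic)
#'
#' Processes a single afferent spike from input neuron `s`:
#' \deqn{h'(i) = \frac{1}{1+\epsilon}\left(h(i) +
#'   \epsilon\,\frac{h(i)W(s|i)}{\sum_j h(j)W(s|j)}\right)}
#' The update is multiplicative, so components at exactly zero stay zero,
#' and it preserves normalization.  `eps` acts as the rate constant of a
#' low-pass filter: the larger, the stronger one spike's impact and the
#' sparser the resulting latent code.
#'
#' @param h Latent probability vector of the population.
#' @param s 1-based index of the afferent input neuron that spiked.
#' @param W Weight matrix (rows: input neurons, columns: population neurons).
#' @param eps Positive smoothing parameter.
#' @return Updated latent probability vector.
#' @export
h_update <- function(h, s, W, eps) {
  w <- W[s, ]
  denom <- sum(h * w)
  if (denom <= 0) {
    stop("degenerate support: spike unexplained by current h and W")
  }
  h2 <- (h + eps * h * w / denom) / (1 + eps)
  h2 / sum(h2)
}

#' Generative reconstruction of the input distribution
#'
#' `r(s) = sum_i h(i) W(s|i)`: the population's internal model of its input.
#' Because columns of `W` are normalized, `r` is itself a probability vector.
#'
#' @param h Latent probability vector.
#' @param W Weight matrix.
#' @return Probability vector over the input neurons.
#' @export
reconstruct <- function(h, W) {
  if (ncol(W) != length(h)) stop("shape mismatch between W and h")
  as.vector(W %*% h)
}

#' Cross-entropy between an observed and a reconstructed distribution
#'
#' `-sum_s p_hat(s) log r(s)` with natural logarithm; terms with
#' `p_hat(s) = 0` contribute zero.  Returns `Inf` when `p_hat` has mass
#' where `r` has none.
#'
#' @param p_hat Observed (spike-count estimated) probability vector.
#' @param r Reconstruction probability vector.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
cross_entropy <- function(p_hat, r) {
  on <- p_hat > 0
  if (any(on & r <= 0)) return(Inf)
  -sum(p_hat[on] * log(r[on]))
}

#' Estimate an input distribution from observed spikes
#'
#' `p_hat(s) = count(s) / T` after observing `T` spikes.
#'
#' @param events Integer vector of 1-based spike indices.
#' @param n_s Number of input neurons.
#' @return Probability vector of length `n_s`.
#' @export
estimate_p_from_spikes <- function(events, n_s) {
  if (length(events) == 0L) stop("degenerate: no spike events observed")
  tabulate(events, nbins = n_s) / length(events)
}

#' Kullback-Leibler divergence between target and output distributions
#'
#' `sum_q zeta(q) log(zeta(q)/h(q))`, with `0 log(0/x) = 0`.  Used as the
#' training-progress measure between the desired output `zeta` and the
#' output population's latent variables.
#'
#' @param zeta Target probability vector.
#' @param h Output probability vector.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
kl_divergence <- function(zeta, h) {
  on <- zeta > 0
  if (any(on & h <= 0)) return(Inf)
  sum(zeta[on] * log(zeta[on] / h[on]))
}

#' On/off encoding of pixel intensities
#'
#' Splits a scalar intensity `P` in \[0, 1\] into two rectified channels,
#' `I_ON = max(2P - 1, 0)` and `I_OFF = max(1 - 2P, 0)`, forming a
#' two-neuron input module that carries positive activity also for dark
#' pixels.  At `P = 0.5` both channels are zero and the module is
#' degenerate: it emits no spikes.
#'
#' @param P Numeric vector (or matrix) of intensities in \[0, 1\].
#' @return Matrix with two columns `on` and `off`, one row per pixel.
#' @export
on_off_encode <- function(P) {
  if (any(P < 0 | P > 1)) stop("intensities must be scaled to [0, 1]")
  p <- as.vector(P)
  cbind(on = pmax(2 * p - 1, 0), off = pmax(1 - 2 * p, 0))
}
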