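---
title: "Spike-by-Spike networks: model, learning rule, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-by-Spike networks: model, learning rule, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbsnet)
```

## The model

A Spike-by-Spike (SbS) network is a feed-forward arrangement of *inference
populations* (IPs).  An IP with $N$ neurons carries a latent probability
vector $h(i) \ge 0$, $\sum_i h(i) = 1$, and non-negative weights $W(s|i)$
with $\sum_s W(s|i) = 1$, and interprets its spike input generatively: its
reconstruction of the input distribution is $r(s) = \sum_i h(i)\,W(s|i)$.
The mismatch between the observed input $\hat p(s)$ (the empirical spike
histogram) and $r(s)$ is measured by the cross-entropy
$-\sum_s \hat p(s) \log r(s)$.

Time advances one spike at a time.  Per time step every input module and
every non-output IP draws exactly one spike — a single categorical draw of
the index of the next firing neuron, which is the Bernoulli-process reading
of "which neuron fires next" — and every IP folds each afferent spike
$s^t$ into its latent state through the multiplicative h-dynamic
$$h^{t}(i) = \frac{1}{1+\epsilon}\left(h^{t-1}(i) + \epsilon\,
  \frac{h^{t-1}(i) W(s^t|i)}{\sum_j h^{t-1}(j) W(s^t|j)}\right).$$
The update is exactly normalization-preserving, keeps zero components at
zero (which dropout exploits, see below), and for identity weights and a
constant input spike $s_0$ contracts the off-target mass geometrically:
after $T$ steps it equals $(1 - h^0(s_0))(1+\epsilon)^{-T}$ — a closed form
the test suite asserts to $10^{-10}$.

$\epsilon$ is the temporal integration rate: the larger it is, the more one
spike moves the state and the sparser the latent code.  The default base
value is $\epsilon_0 = 0.1$.  In deep architectures each layer uses
$\epsilon_0$ divided by the number of spikes the IP receives per time step
(its fan-in), so all layers move at comparable speed per step; the deep
28×28 architecture follows the divisor table (1, 4, 25, 4, 16, 1) — the
first convolutional layer keeps divisor 1 even though its fan-in is 25,
which we adopt verbatim as configuration since the divisors are exposed per
layer.  An optional schedule divides $\epsilon_0$ by 25 after 1,000 time
steps, turning the remaining spikes into an implicit average of the latent
variables.

## The learning rule

Training minimizes $E = -\sum_\mu \sum_q \zeta_\mu(q) \log h_y(q)$ over the
output population $y$, with $\zeta$ the desired output distribution.  The
gradient of one pattern with respect to the weight block between an
upstream population $A$ and its downstream population $B$ is
$$\omega(q,q') = F(q,q')\Bigl(R(q)\,\Phi(q') - \sum_j r(q,j)\,\Phi(j)\Bigr),$$
with $r(q,q') = h_B(q') W(q|q')$, $R(q) = \sum_j r(q,j)$,
$F(q,q') = h_A(q)\,h_B(q')/R(q)^2$, and the backward error $\Phi$ seeded at
the output as $\Phi_y(q) = \frac{\epsilon}{1+\epsilon}\,\zeta(q)/h_y(q)$
and propagated upstream through
$$\Phi_A(q) = \frac{\epsilon}{1+\epsilon}\,
  \frac{\sum_{q'} \Phi_B(q')\,h_B(q')\,W(q|q')}{\sum_j h_B(j)\,W(q|j)}.$$

Two aspects distinguish this from ordinary backpropagation:

* **Time retardation.**  The latent variables feeding the rule come from
  progressively earlier time steps for layers progressively farther from
  the output: a downstream population at distance $m$ from the output
  contributes its snapshot from time $T-m$ to the formation of its own
  $\Phi$ and its snapshot from $T-m-1$ to $r$, $R$, $F$ and to the backward
  step into its upstream layer.  The simulation records the trailing
  (depth+1) snapshots of all populations for this purpose.  A
  retardation-off mode uses the final state everywhere; it changes only
  which snapshots are read, not shapes or normalization, and still learns
  the parity task at reduced scale.
* **Multiplicative, normalized updates.**  With the accumulated gradient,
  weights move as $V = W\,(1 - \frac{\gamma}{S}\,\partial E/\partial W)$
  with $S = \max|\partial E/\partial W|$ taken over the weight group, are
  floored at $\Theta = 10^{-4}$, and column-renormalized.  The scale guard
  makes the update safe for any $\gamma < 1$; the floor prevents the
  multiplicative rule from locking entries at zero.

Three indexing and scoping choices in the rule were genuinely open and are
resolved as follows:

* The factor $\epsilon/(1+\epsilon)$ in the $\Phi$ equations uses the
  effective $\epsilon$ of the layer whose latent variables appear in that
  factor (the downstream population).  When layers differ in $\epsilon$,
  this is the only reading consistent with the derivative of that layer's
  h-dynamic.  With the epsilon schedule active, the value in effect at the
  final simulated step is used, matching the snapshots the rule consumes.
* $S$ is computed per weight-sharing group after all pattern and position
  contributions are combined, because that is the matrix actually updated.
* Contributions of spatial positions that share one convolutional weight
  matrix are averaged by default (as the split parity network prescribes);
  plain summation is available as `mode = "sum"` — the two differ only by
  an effective learning-rate factor.

The vectorized batch implementation folds all per-pattern outer products
into matrix products; an independently written nested-loop oracle
(`gradient_oracle_naive()`) recomputes the same quantities element by
element, and the suite requires agreement to $10^{-10}$ on random
micro-networks, including weight-sharing cases.

## The mini-batch optimizer

For larger architectures plain gradient descent is improved by an optimizer
that works per mini-batch (default 10% of the training set, drawn uniformly
without replacement, fresh each step):

1. Z-transform: $Z = (-\partial E/\partial W)\odot W$.
2. Bias-corrected exponential smoothing of $Z$ and of the output
   Kullback-Leibler divergence, with $\hat Y(L) = \hat Y(L-1)(1-1/\tau) +
   Y(L)/\tau$ and $Y^*(L) = \hat Y(L)/(1-(1-1/\tau)^L)$; $\tau = 10$
   matches the 10% mini-batches.  $Y^*(1) = Y(1)$ exactly, and a constant
   sequence is reproduced exactly at every $L$.
3. Learning rate $\gamma(L) = \gamma_0 \sqrt{KL^*(L)/KL_{max}}$ with
   $\gamma_0 = 0.05$ and $KL_{max}$ the running maximum of $KL^*$; the
   square root keeps the rate high early on.  Since $KL_{max}$ is updated
   before $\gamma$, $\gamma(1) = \gamma_0$ exactly.
4. Update $V = W + \frac{\gamma}{S} Z^*$ with $S = \min(\max|Z^*|, 1)$ per
   group, floored elementwise at $\max(\Theta, W/2)$ — no weight loses more
   than half its value per step — then column-normalized.

The order accumulate → Z → smooth → KL → rate → update is the only causally
consistent sequence and is fixed in the implementation.  Whether the
smoothing state and $KL_{max}$ survive stage boundaries is unspecified in
the protocol; we reset them per stage (each stage re-randomizes some weight
groups, after which stale statistics would be misleading), so the rate
restarts at $\gamma_0$.

Dropout is implemented by initialization: before a pattern, each neuron of
the configured layer is enabled with probability $\beta$ (all-disabled
draws are redrawn), the latent vector is uniform over enabled neurons and
exactly zero elsewhere, and the multiplicative h-dynamic keeps disabled
neurons silent for the entire presentation.  The mask is redrawn for every
pattern presentation; $\beta$ starts small (16/1024 for the deep
architecture's fully connected layer) and doubles every 30 mini-batches
until it reaches 1.

## Tasks and the synthetic generator

The Boolean tasks are exact: XOR (4 patterns, one 4-neuron input module)
and 4-bit parity (16 patterns; either one 8-neuron module or the split
encoding with two 4-neuron modules whose first-layer weights are shared).
Inputs are exact distributions — stochasticity enters only through the
spike draws of the simulation.  The staged parity protocol halves the
spikes per pattern across stages (1,024/512/256/128) and halves $\gamma$
within each stage every 1,000 steps starting from 0.03; the deliberate
increase in spike noise across stages forces weight sets that are robust to
degraded representations.

The synthetic image task generates single-bar images (horizontal vs
vertical, random position, optional pixel-flip noise) and on/off encodes
each pixel as $I_{ON} = \max(2P-1, 0)$, $I_{OFF} = \max(1-2P, 0)$.  It
emulates the structure of the image benchmark — two-channel rectified
input modules, a shared-weight convolutional layer, argmax decoding — at a
size where a full training run takes seconds.  It does **not** emulate
gray-value statistics, class overlap, or the depth of the full
architecture, so passing it demonstrates that convolutional weight sharing
and the learning rule compose correctly, not that the package reproduces
full-scale image benchmarks.  The full 28×28 architecture itself is built
and verified structurally (grid sizes 28×28 → 24×24 → 12×12 → 8×8 → 4×4 →
1 → 1; neurons 2/32/32/64/64/1024/10; fixed feature-block pooling weights),
but training it at full scale is outside the test suite's scope.

A mid-gray pixel ($P = 0.5$) yields a degenerate all-zero input module.
How such a module behaves is not specified by the encoding; we let it emit
no spike for that time step and contribute nothing downstream, which is the
minimal consistent choice given that the h-dynamic has no likelihood for a
non-event.  The simulation record counts skipped updates so degenerate
inputs remain visible.

## Numerical choices

* All probability arithmetic is double precision; latent vectors are
  renormalized after every update, and weight matrices after every weight
  update, absorbing drift (asserted to $10^{-12}$ over 10,000 random
  updates).
* Argmax decoding breaks ties toward the lowest index, making degenerate
  (uninformative) networks decode deterministically.
* Weight initialization is $V = 1 + 0.01\,U[0,1]$ column-normalized:
  near-uniform columns whose small asymmetries seed the within-population
  competition.  Exactly uniform weights are a fixed point of the dynamics
  (the uniform-likelihood identity), which is why the perturbation is
  essential.
* Random draws run through R's global RNG, both in R helpers and inside
  the C++ kernel (inverse-CDF categorical draws), so a single `set.seed()`
  makes entire training runs bit-reproducible.
* Degenerate supports in the backward recursion ($R(q) = 0$ with a
  non-zero numerator) raise errors rather than propagating non-finite
  values; $0/0$ contributions are defined as 0.

## Problem sizes in the test suite

The suite exercises the full protocols at reduced scale, chosen so the
whole suite runs in minutes on one core: XOR convergence over 25 seeds and
32 learning steps; the parity split-vs-unsplit comparison over 20 seeds ×
1,500 stage-A steps per variant (the full protocol's 4 stages × 7,000
steps × 250 seeds is a cluster-scale experiment and its printed failure
rates are not desk-scale targets); the bar task with 20 patterns, 200
spikes per pattern and 40 learning steps; oracle equivalence on 50 random
micro-networks.  These sizes are fixed choices of the package, not tuned
quantities.

## Known limitations

* Only feed-forward topologies; no recurrent or bidirectional spike flow.
* Poisson real-time spike trains and continuous-time membrane dynamics are
  out of scope by construction of the model.
* The pooling layer is competition through fixed weights, not an
  arithmetic max; with pathological inputs (all features equally active)
  it pools noise.
* Full-scale image-benchmark training is supported by the architecture and
  optimizer code paths but is computationally far beyond a test suite; the
  package validates those paths on the synthetic task instead.
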