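# sbsnet

Simulation and supervised training of **Spike-by-Spike (SbS) networks** in R.

## The problem

Spike-by-Spike networks sit between conventional artificial neural networks
and biologically detailed spiking models.  Their building block is not a
single neuron but an *inference population* (IP): a group of neurons whose
non-negative, normalized latent variables `h(i)` form a generative model of
the population's spike input.  Simulated time advances one exchanged spike
at a time — the only signal that travels between populations is the index of
the neuron that fired — which makes the model event-driven, cheap to
simulate, and naturally parallel.

An IP with weights `W(s|i)` (columns normalized over the input neurons `s`)
represents its input distribution `p(s)` by the reconstruction

    r(s) = sum_i h(i) W(s|i)

and updates its latent variables once per incoming spike `s^t` with the
multiplicative *h-dynamic*

    h'(i) = (1 / (1 + eps)) * ( h(i) + eps * h(i) W(s^t|i) / sum_j h(j) W(s^t|j) )

where `eps > 0` controls how strongly one spike moves the state (and, with
it, the sparseness of the latent code).  Stacking IPs into feed-forward
layers — dense, convolutional, and pooling layers all made of the same
primitive — gives a deep network that classifies by the argmax of its output
population.

Training deep SbS networks is the hard part: the package implements an
error-backpropagation learning rule for the cross-entropy objective
`E = -sum_mu sum_q zeta(q) log h_y(q)` in which the backward quantity `Phi`
propagates not only from layer to layer but also *back in time*, reading
latent-variable snapshots from progressively earlier time steps for layers
progressively farther from the output.  Per weight group, contributions

    omega(q,q') = F(q,q') * ( R(q) Phi(q') - sum_j r(q,j) Phi(j) )

are accumulated over patterns (and spatial positions of shared convolutional
weights) into `-dE/dW`, and the weights are moved by a normalized
multiplicative update with a scale guard `S = max|dE/dW|`, a floor
`Theta = 1e-4`, and column renormalization, so they always remain
non-negative conditional probabilities.  A mini-batch optimizer adds
bias-corrected exponential smoothing of the gradients, a learning rate
modulated by the smoothed output Kullback-Leibler divergence, and dropout
implemented purely by initializing latent variables to zero.

The package ships the classical test beds for this model family: the XOR
task, the 4-bit parity task (with the split-layer variant that shares
weights between its two half-populations), a synthetic bar-image task for
convolutional architectures, the full 28x28 on/off → conv → pool → conv →
pool → dense → output digit-classification architecture, and a reader for
IDX (ubyte) image files.

## Worked example: learning XOR

```r
library(sbsnet)
set.seed(1)
net <- build_xor_network()
net
#> Feed-forward SbS network: 3 layers, 3 populations, 10 neurons
#>   X        input  grid 1x1, 4 neurons/pop, eps/1
#>   H1       dense  grid 1x1, 4 neurons/pop, eps/1
#>   HY       output grid 1x1, 2 neurons/pop, eps/1
#> Weight groups: W_X_H1, W_H1_HY

dataset <- make_xor_dataset()
fit <- train_simple(net, dataset,
                    training_schedule(schedule_stage(10, 1024, 0.025)))
round(fit$log[c(1, 2, 4, 6, 10), c("step", "gamma", "objective", "train_error")], 4)
#>    step gamma objective train_error
#> 1     1 0.025    2.7789        0.25
#> 2     2 0.025    2.9960        0.50
#> 4     4 0.025    2.3859        0.25
#> 6     6 0.025    0.2054        0.00
#> 10   10 0.025    0.0007        0.00

evaluate_network(fit$net, dataset, spikes = 1024)
#> $error
#> [1] 0
#> $predicted
#> [1] 1 2 2 1
#> $truth
#> [1] 1 2 2 1
```

Each learning step simulates all four patterns for 1,024 spikes, accumulates
the batch gradient of the backprop rule, and applies the multiplicative
update with `gamma = 0.025`.  The `objective` column is the output
cross-entropy summed over the batch; `train_error` is the fraction of
patterns whose output population decodes to the wrong class.  Within a
handful of steps the competition inside the hidden and output populations
amplifies the small random asymmetries of the initial weights into a perfect
solution.

Configuration-driven runs (training log, weight checkpoint, and manifest in
an output directory) are available through `run_train()`/`run_eval()` or the
wrappers in `inst/scripts/`:

```sh
Rscript inst/scripts/sbs-train.R --config cfg.yaml --seed 1 --out runs/xor
```

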