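---
title: "Neural generative coding: model, dynamics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural generative coding: model, dynamics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gncn)
```

## The generative model

A generative neural coding network (GNCN) is a hierarchy of `L + 1` layers of
state neurons `z^0, ..., z^L`, with `z^0` clamped to the data `x`. The network
encodes a directed latent-variable model
`P(z^0 | z^1) P(z^1 | z^2) ... P(z^L)`: each layer predicts the one below it,

    zbar^l = g^l( W^{l+1} phi(z^{l+1}) + alpha_m * M^{l+2} phi(z^{l+2}) ),

where `W` are generative synapses, the optional `M` matrices add a
skip-prediction path from two layers up (the "partially decomposable
hierarchy", `alpha_m = 1`), `phi` is the state nonlinearity and `g` the
prediction nonlinearity. For binary pixels the output layer is Bernoulli with
mean `zbar^0 = sigmoid(h^0)`; every hidden conditional is Gaussian with mean
`zbar^l` and learnable precision `Prec^l = (Sigma^l)^{-1}`. The top layer has
no top-down prediction; its zero-mean Gaussian prior is realized by the leak
term of the dynamics.

The objective is the complete-data log-likelihood, the *total discrepancy*

    psi = sum_j [ x_j log zbar^0_j + (1 - x_j) log(1 - zbar^0_j) ]
        + sum_{l=1}^{L-1} [ 1/2 log|Prec^l| - 1/2 m_l' Prec^l m_l ],
    m_l = z^l - zbar^l,

a (negated) free energy: inference and learning both ascend `psi`. Note the
sign of the log-determinant: it is the one consistent with the precision
gradient `d psi / d Prec = 1/2 Sigma - 1/2 m m'`, whose stationary point is
the empirical mismatch covariance — the property the precision update and its
tests rely on.

*Error neurons* carry the mismatch signals: `e^0 = x - zbar^0` for a sigmoid
output (the exact folded form of the Bernoulli ratio
`x / zbar - (1-x)/(1-zbar)` through the sigmoid derivative; both forms are
implemented and their identity is tested), and
`e^l = Prec^l (z^l - zbar^l)` for hidden layers: each layer's own precision
weights its own mismatch. A `"shifted"` re-indexing of the same quantities is
available in `ngc_errors()` for comparison with conventions that attach the
error vector to the layer above; the dynamics always consume the layer-local
form.

## Settling and learning

Inference is a `T`-step relaxation (`ngc_settle()`). Per step, in Jacobi
order — project all layers top-down, evaluate all error neurons, then update
every hidden state simultaneously:

    z^l <- z^l + beta * ( E^l e^{l-1} - e^l  - lateral - gamma z^l
                          [- lambda sign(z^l)] )

The Jacobi ordering makes trajectories independent of the order in which
layers are visited. Error-feedback synapses `E` are either learned ("Type 2")
or virtual transposed views of `W` ("Type 1"); Type-1 models additionally
multiply the error-correction bracket elementwise by `phi'(z^l)`. After
settling, all synaptic updates are local outer products of an error and an
adjacent activity:

    dW^l = e^{l-1} phi(z^l)'      (batch-averaged)
    dE^l = lambda * phi(z^l) e^{l-1}'      (Type 2; no phi-derivative)
    dM^l = e^{l-1} phi(z^{l+1})'

followed by a gradient-ascent precision step (symmetrized and
eigenvalue-floored to stay positive-definite) and column normalization of the
generative matrices to unit Euclidean norm. Training (`ngc_train()`) is plain
minibatch SGD over shuffled epochs; all randomness flows from the config
seed, so a fixed seed reproduces the parameter trajectory bit for bit.

The exact gradients of `psi` (with the full activation-derivative chain) are
implemented separately (`ngc_grad_z()`, `ngc_grad_W()`, `ngc_grad_M()`) and
serve as the oracle against which the local rules are checked by central
differences. Two facts the tests exploit: the Hebbian `dW` *is* the exact
gradient (the output derivative is folded into `e^0`), and the Type-1 state
delta coincides with the exact gradient at the zero-initialized fresh state
(where `tanh' = 1`) and at the top layer at any state. At other states the
printed Type-1 rule scales the top-down term by `phi'` as well, which the
exact gradient does not — a deliberate feature of the rule, not an error.

## The four variants

`make_variant()` configures the generic engine:

| variant | error synapses | phi | precisions | extras |
|---|---|---|---|---|
| GNCN-t1/Rao | `E = t(W)` (virtual) | tanh | fixed spherical | `gamma = 0`, phi-derivative on |
| GNCN-t1-Sigma/Friston | `E = -t(W)` (virtual) | relu | learned | kurtotic prior |
| GNCN-t2-LSigma | learned | relu | learned | group-competition lateral `V` |
| GNCN-PDH | learned | relu | learned | lateral `V` + skip matrices `M` |

One convention deserves a note. In the model family that the
negative-transpose variant descends from, error units signal
*prediction minus target*; combining `E = -t(W)` naively with this package's
`e = Prec (z - zbar)` convention would make the bottom-up message point
*down* the likelihood gradient and the dynamics diverge within a few steps.
The implementation therefore flips the sign of the upward message for the
negative-transpose error type, so that `E . message` points up the gradient
while the stored synapses keep the defining `E == -t(W)` identity. This is a
sign-convention reconciliation, not a change of model.

Lateral group competition wires each hidden layer with a block-diagonal `V`:
within consecutive groups of `K` neurons, off-diagonal inhibition and
diagonal self-excitation. Two update forms are provided: the explicit
excitatory/inhibitory split over `phi(z)` (default) and a plain `-V z` term
(`lateral_form = "linear"`). The coefficients default to self-excitation 0.1
and inhibition 0.2: self-excitation enters the update as a positive feedback
`+beta * V_ii * phi(z_i)` compounded over `T = 50` steps, so values near 1
amplify activity by two orders of magnitude and destabilize settling;
keeping self-excitation below within-group inhibition sharpens one winner
per group without runaway growth.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.1 | state step size per settling iteration |
| `gamma` | 0.001 | leak; scale of the zero-mean Gaussian state prior |
| `lambda_prior` | 0.01 | kurtotic (sparsity) pressure, Friston variant |
| `n_steps` (T) | 50 | settling iterations per presentation |
| `weight_lr` | 0.01 | SGD step on synapses |
| `lambda_err` | 0.9 | error-synapse rate (< 1, Type 2) |
| `batch_size` | 200 | records per update |
| `init_sd` | 0.05 | Gaussian weight initialization scale |

`T = 50` and the batch size follow the reference training protocol; `beta`
and `gamma` are free parameters chosen small enough that the energy-descent
property holds with margin, and exposed in the config. Weight initialization
is zero-mean Gaussian followed by one column normalization (error synapses
are normalized only at initialization; re-normalizing them during training
would cancel the `lambda_err < 1` rate).

## Numerical choices

* Bernoulli means are clipped into `[1e-6, 1 - 1e-6]` so the likelihood and
  its logs stay finite; the raw-ratio error form refuses unclipped 0/1 means.
* `sign(0) = 0` for the kurtotic prior (standard subgradient); the relu
  derivative at 0 is taken as 1 so that zero-initialized states of Type-1
  relu models can move at all.
* Settling aborts with a diagnostic when any activity exceeds `1e6` in
  magnitude (divergence guard).
* Precision matrices are kept positive-definite by symmetrization plus an
  eigenvalue floor (`1e-4` by default); full and diagonal modes exist, with
  full as the default.
* Batch updates are averaged, not summed, so step sizes are invariant to the
  batch size.
* The precision update runs once per batch after the weight updates whenever
  precisions are declared learned; the Rao variant keeps them fixed.
* The skip-matrix update `dM` follows the same Hebbian template as `dW` with
  the corresponding presynaptic activity; the model family does not prescribe
  a separate rule, and this choice makes `dM` the exact gradient of `psi`
  along the skip path.
* Biases are omitted throughout.
* The `log-mean-exp` in the Monte-Carlo likelihood estimator is max-shifted
  for stability.
* Sparsity `rho_a^l` counts states `z_i^l > 1e-6` on the pre-activation
  state itself, not `phi(z)`.

## The synthetic generator and what the tests show

`synth_generate()` draws top-layer codes from a small Gaussian mixture (the
components act as known classes), maps them linearly through a random
column-normalized matrix, squashes with a tempered sigmoid
(`noise` = temperature; means saturate to {0, 1} as it approaches 0), and
samples Bernoulli pixels. Defaults: `D = 16`, `J1 = 8`, four classes, class
spread 1.0, within-class latent sd 0.5, temperature 0.4 — moderate noise,
enough class structure for probe tests. The generator uses a *linear* latent
path precisely so that its pixel marginals reduce to one-dimensional Gaussian
integrals, evaluated by Gauss–Hermite quadrature
(`synth_marginal_means()`), giving the sampling tests an independent
closed-form target.

The generator emulates the model family's assumed data-generating process:
hierarchical Gaussian latents with a Bernoulli output. It does *not* emulate
the spatial correlation structure, stroke topology, or class imbalance of
real handwritten-character images. Passing the recovery, completion and
sparsity tests therefore demonstrates that the machinery optimizes what it
claims to optimize under its own model class — not that it attains any
particular benchmark number on real image corpora, which requires external
data and long CPU training (supported through the CLI and config, but not
part of the test suite).

Two experiment-design points:

* **Energy descent** is measured on linear-Gaussian networks (identity
  output), where the whole of `-psi` is the quadratic mismatch energy and
  settling is exactly gradient descent on it. With a Bernoulli output and
  zero-initialized latents the Gaussian portion starts at its global minimum
  (zero) and must transiently rise while the output term improves, so the
  monotone-descent property is only meaningful in the all-Gaussian setting.
* **Pattern completion** is evaluated on a strongly clustered, near-
  deterministic generator configuration (`D = 64`, class spread 1.5, latent
  sd 0.25, temperature 0.25). Completion skill can only be measured when the
  masked half is predictable from the observed half: under the looser default
  configuration even the generator's own true means beat a 0.5-constant fill
  on barely 90% of patterns, i.e. the comparison saturates at the Bayes
  ceiling and discriminates nothing. The clustered configuration lifts that
  ceiling to ~98% and leaves room for an inference method to demonstrate
  skill. The recovery experiment trains a two-layer relu Type-2 model: with
  unit-norm columns and a bounded `tanh` state the saturated generator means
  are unreachable, whereas relu states scale freely.

Problem sizes throughout the suite (latent widths 2–12, data widths 4–64,
2000-record training sets, 5–30 epochs) are chosen so that each experiment
is a sharp, fully reproducible property check.

## Sampling, completion, evaluation

After training, `fit_prior()` collects the settled top-layer code of every
training record and fits a `K`-component Gaussian mixture to them by EM (the
reference configuration uses `K = 75`; small runs use fewer). Ancestral
sampling draws a code from the mixture and propagates means down the
hierarchy — no settling involved; the output is the mean image.
`complete_pattern()` treats the clamped layer as a partial latent state:
observed pixels stay fixed while missing ones relax toward the top-down
prediction through the output error neurons, interleaved with latent settling
(latent step first, then output step; completion iterations default to the
settling budget `T`).

Metrics: reconstruction BCE (nats, summed over pixels, averaged over
records); a Monte-Carlo marginal log-likelihood (log-mean-exp over ancestral
samples, 5000 by default); masked MSE restricted to unobserved entries,
averaged over records (the per-record vector form is ambiguous about
aggregation, and averaging matches the other metrics); classification error
of a multinomial-logistic probe on frozen codes, with probe training and
evaluation on disjoint code sets; and per-layer activity sparsity.

## Known limitations

* The settling loop is plain R matrix algebra; it is fast for the desk-scale
  networks used here but a 784-pixel, 50-epoch run is a long CPU job.
* Full-covariance precisions are `O(J^2)` per layer; use the diagonal mode
  for wide layers.
* The mixture prior is fit post hoc, as in the reference procedure; nothing
  constrains the settled codes to be mixture-distributed during training.
* Signum states are only usable in Type-2 models (their updates need no
  `phi` derivative); the kurtotic prior and group competition are alternative
  sparsity mechanisms and are not combined in any preset.
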