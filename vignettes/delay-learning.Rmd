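---
title: "Joint weight and delay learning in spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint weight and delay learning in spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`delayprop` simulates and trains feed-forward networks of Spike Response
Model (SRM) neurons in which every synapse carries two learnable
parameters: an efficacy $w_{ij}$ and a transmission delay $d_{ij}$.  The
membrane potential of neuron $j$ in layer $l+1$ is a delayed, weighted sum
of stereotyped postsynaptic potentials (PSPs):

$$V_j^{l+1}(t) = \sum_i w_{ij}^{l+1}\, K\!\left(t - t_i^l - d_{ij}^{l+1}\right),$$

where $t_i^l$ is the (single) firing time of presynaptic neuron $i$ and the
kernel is the causal double exponential

$$K(x) = V_{norm}\left[e^{-x/\tau_m} - e^{-x/\tau_s}\right],\quad x > 0,$$

zero for $x \le 0$.  With $\beta = \tau_m/\tau_s$ the normalization
$V_{norm} = \beta^{\beta/(\beta-1)}/(\beta-1)$ scales the kernel peak to
exactly 1, so weights are interpretable as peak PSP amplitudes.  A neuron
fires the first time its potential reaches the threshold $\vartheta$ and is
then frozen for the rest of the window: every neuron spikes at most once
per sample, and all information lives in *when* it spikes.

Training minimizes the temporal mean squared error
$E = \tfrac12\sum_k (t_k^{o} - t_k^{d})^2$ between actual and desired
output spike times.  Backpropagation through spike times yields, per
synapse,

$$\Delta w_{ij}^l = -\eta_w\, \delta_j^l\, K_{ij}^l, \qquad
  \Delta d_{ij}^l = -\eta_d\, \delta_j^l\, w_{ij}^l\, \xi_{ij}^l,$$

where $K_{ij}^l$ is the unweighted PSP evaluated at the postsynaptic firing
time, $\xi_{ij}^l = \partial K/\partial d_{ij}^l = -\,dK/dx$ couples a
delay to the downstream crossing, and the error term $\delta_j^l$ chains
the spike-time derivative $\partial t_j^l/\partial V$ with either the
output error or the upstream $\delta$'s.  `psp_delay_deriv()` implements
$\xi$ and the identity $\xi \equiv -$`psp_kernel_deriv()` is enforced by
test.

## The spike-time derivative and its surrogate

The classical linearization treats the potential as locally linear at the
crossing, $\partial t/\partial V = -1/\dot V(t)$.  It is exact to first
order but explodes when the potential grazes the threshold slowly
($\dot V \to 0$).  The package's default replaces its magnitude by a capped
Gaussian in the at-crossing potential:

$$\left|\frac{\partial t}{\partial V}\right| =
\begin{cases}
\exp\!\big(-2 (V - \vartheta)^2/\tau_{sg}\big), & |V - \vartheta| > m,\\[4pt]
\exp\!\big(-2 m^2/\tau_{sg}\big), & |V - \vartheta| \le m,
\end{cases}$$

continuous at the branch point and bounded by the cap, so no crossing can
blow the gradient up.  Two conventions had to be decided:

* **Sign.**  The capped Gaussian is positive while the linearized
  derivative is negative at an upward crossing.  The surrogate supplies the
  magnitude; backpropagation applies $\partial t/\partial V =
  -\,$`surrogate_dtdv()`, preserving the descent direction of the
  linearized rule.
* **Hyperparameters.**  $m$ (default 0.3) and the temperature $\tau_{sg}$
  (default 1.0) are independent knobs; neither is tied to the membrane
  constants, and both are exposed for per-task search.

`linearized` mode is retained, for comparison studies and because it is the
only mode in which analytic gradients can be compared against finite
differences (`gradcheck()`): the surrogate *intentionally* disagrees with
the true derivative, so a surrogate-mode gradient check is reported as
non-comparable rather than as a failure.

## Discretization and numerical choices

The simulator runs on a uniform closed grid `[0, t_end]` with step `dt`
(defaults 25 ms and 0.1 ms).  Spike times are reported at grid points,
which keeps runs exactly reproducible; an optional linear-interpolation
refinement of the crossing is available and off by default.  The gradient
checker is the exception: it always interpolates and uses a finer grid
(`dt = 0.01` ms), because on a coarse grid a small parameter perturbation
usually does not move the crossing at all and the finite-difference oracle
would be identically zero.  Central differences with `h = 1e-3` then agree
with the analytic gradients to about 1% relative error away from firing
flips; coordinates whose perturbation flips any neuron's firing status are
excluded (spike time is genuinely discontinuous there) and counted
separately.

Default constants: $\tau_m = 10$ ms, $\tau_s = 2.5$ ms, $\vartheta = 1$,
delays clamped to $[0, d_{max} = 10]$ ms after every update, weights
unconstrained in sign.  Initialization draws weights uniformly from a
positive range scaled so a fresh postsynaptic neuron's expected peak
potential is about $1.5\vartheta$ (keeping early layers responsive without
saturating) and delays from $[0, d_{max}/2]$.

**Silent neurons.**  A neuron that never crosses threshold transmits no
spike and blocks gradient flow.  The package applies a two-part policy: a
silent *output* neuron enters the loss with the surrogate time
`t_end + silent_margin` (silence is an extreme late spike), and every
silent neuron *with downstream demand* has all incoming weights boosted by
a fixed `silent_boost` before the next sample, nudging it back into the
responsive regime.  Hidden neurons always carry demand; a silent output
neuron is boosted only when its desired time asks for a spike strictly
inside the window — a non-target trained toward the window edge is silent
by design and is left alone.  Gradient entries attached to silent neurons
are exactly zero.

**Updates.**  Training is online: the data set is reshuffled every epoch
with the run seed and parameters are updated after every sample.  An
optional multiplicative per-epoch learning-rate decay (`eta_decay`)
anneals the online updates; the default task configuration uses 0.99.
The `weight_only` switch freezes all delays, giving the classical
weight-only learner as an ablation; everything else is held identical so
paired comparisons isolate the contribution of delay plasticity.

## Encoding and decoding

Real-valued features are population-encoded: each feature drives
`neurons_per_feature` (default 6) neurons with overlapping Gaussian
receptive fields laid out over the feature's training range, plus one
always-on reference neuron at $t = 0$ per sample, so four features map to
$6 \times 4 + 1 = 25$ input neurons.  A stronger receptive-field response
means an earlier spike, linearly in $(1 - r)\,t_{window}$; responses below
`fire_cutoff` (default 0.1) emit nothing, so the far edge neurons stay
silent.  Image intensities use latency encoding: brighter pixels fire
earlier, zero pixels not at all (`read_idx()` reads the standard IDX
raster layout for such experiments).

Class labels become desired time vectors: the target neuron is asked to
fire early (`t_early`, default 14 ms), all others late (`t_late`, default
25 ms — the end of the default simulation window).  Asking non-targets for
a *late* time rather than excluding them from the loss keeps the loss
defined for every output neuron while still expressing "keep the others
quiet"; placing that time at the window edge matters, because it drives
trained non-targets to the boundary between firing last and not firing at
all, which is the regime the firing-count decision rule is built for.  An
interior `t_late` trains non-targets to fire reliably *within* the window,
every sample then ties on spike count, and the decision degenerates to the
timing-blind membrane-potential comparison.  A `dynamic` mode that pulls the
target time just ahead of the network's current earliest output spike is
available as a stand-in for adaptive target-assignment schemes; the static
rule is the default because it makes runs reproducible without reference
to the network state.

Decoding follows the firing-count-then-potential rule: the predicted class
is the output neuron with the most spikes (under the one-spike constraint:
firing beats silence); among equal counts the largest membrane-potential
maximum wins, and exact ties go to the lowest index so the rule is total.
For single-output tasks (temporal XOR) `decoder_nearest_time()` assigns
the class whose desired time is nearest the actual output spike.

## What the synthetic generators emulate

Three seeded generators stand in for the external benchmarks this class of
method is usually evaluated on, so the whole pipeline is testable offline:

* `make_gaussian_classes()` — isotropic Gaussian clusters (default 3
  classes, 4 features, 50 samples per class, pairwise center separation
  4 in within-class-sd units, stratified 50/50 split) emulating the
  shape of small real-valued benchmarks such as Iris.  The split RNG is
  seeded independently of the noise RNG, so changing noise never
  reshuffles membership.
* `make_delay_coded_task()` — two classes whose spike-count statistics are
  identical by construction; only a fixed per-channel temporal offset
  pattern (default 3 ms on alternating channels, 0.5 ms jitter) separates
  them.  Weight-only learning has no count statistic to exploit, making
  this the cleanest probe of what delay plasticity adds.
* `make_xor_temporal()` — the canonical four-pattern temporal XOR with a
  reference input, the classic sanity task for spike-time learning.

These generators reproduce the *statistical structure* the method assumes
— cluster geometry, pure-timing class differences — but not the feature
correlations, class imbalance, or measurement noise of real data sets, so
passing tests demonstrate that the algorithm works as specified, not that
any particular real-data accuracy will be attained.

## Default task configuration

The defaults in `parse_run_config()` — `eta_w = 0.03`, `eta_d = 0.1`,
`eta_decay = 0.99`, `silent_boost = 0.05`, 300 epochs — are the settings
we selected by parameter search on the Gaussian-cluster task (this family
of methods has no accepted closed-form hyperparameter rule, and per-task
search is the normal practice).  The problem sizes used throughout the
examples and checks (a 25-10-3 network on 75 training samples, 3-5-1 on
the four XOR patterns, 6-8-2 on the delay-coded task) were chosen as the
smallest configurations on which each phenomenon of interest —
class recovery, temporal XOR, the delay-learning advantage — is cleanly
observable.

## Known limitations

* One spike per neuron: no refractoriness, no multi-spike credit
  assignment; fast time-varying inputs must fit a single-latency code.
* A single delayed terminal per neuron pair (not the multi-terminal
  construction some spike-time learners use); delay learning supplies the
  temporal flexibility instead.
* Online updates only — no momentum, minibatching, or regularization — so
  training curves are noisy by construction and learning rates matter.
  Run-to-run variability across training seeds is substantial (several
  accuracy points on the Gaussian-cluster task), as is typical for online
  spike-time learning; multi-trial averages are the meaningful summary on
  real data.
* The membrane constants, threshold, and encoding layout are configurable
  but not learned.

```{r example}
library(delayprop)

tbl <- make_gaussian_classes(seed = 1)
train <- encode_features(tbl[tbl$split == "train", ])
test <- encode_features(tbl[tbl$split == "test", ],
                        ranges = attr(train, "ranges"))

cfg <- parse_run_config()          # package defaults
obj <- config_objects(cfg)
fit <- srm_fit(train, c(25, 10, 3), obj$neuron, obj$sg, obj$tc, obj$grid)

glance(fit)
srm_evaluate(fit, test)
autoplot(fit)
```
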