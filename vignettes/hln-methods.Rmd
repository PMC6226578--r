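---
title: "Hierarchical linear-nonlinear models of dendritic integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical linear-nonlinear models of dendritic integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlnd)
```

## The model

A neuron's subthreshold input-output transformation is modelled as a
hierarchy of simple subunits arranged in a rooted tree, each corresponding
to a contiguous stretch of dendrite. Subunit $j$ receives a set of
presynaptic spike trains $s_i(t)$. Each synapse filters its train with a
temporal kernel, and the subunit sums the filtered inputs:

$$x_j(t) = \sum_{i} w_{ji}\, (s_i * \kappa)(t - \Delta_j;\ \tau_{ji}),
\qquad
\kappa(t;\tau) = H(t)\,\frac{t}{\tau}\,e^{-t/\tau},$$

where $H$ is the Heaviside step, $w_{ji}$ the synaptic weight (mV,
negative for inhibition), $\tau_{ji}$ the kernel time constant (ms) and
$\Delta_j$ a propagation delay shared by the subunit's synapses.
Excitatory synapses may mix two alpha kernels — a fast and a slow
component with independent amplitudes — to capture receptor populations
with different timescales; the slow time constant can optionally be tied
to the fast one through $\tau_{\mathrm{slow}} = 10.4 + 2.8\,
\tau_{\mathrm{fast}}$ ms, which halves the number of shape parameters at
negligible cost in flexibility.

The subunit adds the coupled outputs of its children and applies a
logistic sigmoid:

$$y_j(t) = x_j(t) + \sum_{k \in \mathrm{children}(j)} c_k\, r_k(t),
\qquad
r_j(t) = \frac{1}{1 + e^{-(y_j(t) - \theta_j)}}.$$

The sigmoid's only free parameter is the threshold $\theta_j$: its
effective slope is set by the incoming weights, and its output scale by
the coupling $c_j$, so neither is separately identifiable and neither is a
parameter. Depending on where the input distribution sits relative to
$\theta_j$, the same sigmoid realises sub- or supralinear integration.
The model output — the predicted somatic subthreshold potential — is the
root subunit's (optionally linear) output scaled by its coupling plus an
offset $v_0$:

$$\tilde v(t) = c_1\, r_1(t) + v_0 .$$

For the canonical single-kernel configuration with a nonlinear output
subunit the parameter count is $N_p = 1 + 3N_{\mathrm{syn}} + 2M$
(offset; amplitude, time constant and delay per independently fitted
synapse group; threshold and coupling per subunit). Other configurations
(double kernels, linear output, multiplexing, shared delays) are handled
by explicit enumeration of the optimizer's free parameters
(`hln_n_free_params()`), which is the source of truth for fitting.

**Multiplexing.** A subunit may carry two parallel channels: the same
spike trains filtered by two independent kernel sets, passed through two
independent sigmoids, summed. This lets one dendritic region express two
different nonlinear transformations of the same input at different
timescales. Child subunits feed channel 1; this convention preserves the
additive form of $y_j$ and is a genuine design choice — the alternative
(children feeding every channel) is not implemented.

## Discretisation

Everything runs on a uniform grid (default `dt = 1` ms; bin $k$ covers
$[t_0 + k\,dt, t_0+(k+1)\,dt)$). Spikes are binned to counts and kernels
sampled at integer lags, so filtering is a discrete causal convolution,
computed by FFT at a power-of-two padded length (raw lengths can contain
large prime factors that slow the FFT by orders of magnitude). A
brute-force per-spike summation implementation is kept in the test suite
as the oracle for this engine. Kernels are truncated at
`horizon_tau = 10` times the largest time constant past the onset delay,
which leaves less than $10^{-3}$ of the kernel mass in the discarded
tail; an explicitly configured absolute horizon that fails to reach past
the delay is an error. Delays are rounded to the
nearest bin — sub-bin delays are not identifiable at the grid resolution —
and are therefore fitted by a small grid search rather than by gradient.

## Fitting

Fitting minimises the mean squared deviation between the target voltage
and $\tilde v(t)$ (mV²), optionally plus a log-normal prior penalty (see
below), with `stats::optim`'s BFGS and fully analytic gradients: the
forward sweep caches each channel's input and slope, and a root-first
backward sweep accumulates exact derivatives for amplitudes, log time
constants, thresholds, log couplings and the offset. Gradients are
verified against central finite differences in the test suite. Time
constants, couplings and delays are log- or grid-parameterised, so they
remain positive throughout. The error surface is non-convex, so the fit
is staged:

1. **Coupled stage.** A single-subunit linear model in which all
   excitatory synapses share one (amplitude, time constant, delay) and all
   inhibitory synapses another. Amplitudes and offset are initialised by
   ordinary least squares at the starting time constant (the model is
   linear in them), the delay is chosen by grid search
   (`delay_grid_ms`, default 0–2 ms), and BFGS refines everything. A
   linear root makes this stage's parameters identifiable without scale
   ambiguity, which is why it is used as the anchor for everything that
   follows.
2. **Pretuning and the $\rho$ grid.** The learned kernels seed the target
   architecture. Each nonlinear subunit is then initialised *near its
   linear regime*: weights (and child couplings) are rescaled so the
   subunit's total-input distribution is centred on the sigmoid midpoint
   with standard deviation $1/\rho$, the threshold is set to the input
   mean, and the subunit's output coupling is divided by $0.25 \times$
   the rescale factor (0.25 being the logistic slope at its midpoint), so
   the somatic response amplitude of every synapse —
   $a_{ji} = w_{ji} c_j r_j' \prod_k c_k r_k'$ with slopes at the
   operating point — is exactly preserved relative to the linear model
   being approximated. The offset is adjusted to preserve the mean
   response. As $\rho \to \infty$ the pretuned model converges to linear
   integration pointwise. The model is optimized once per
   $\rho \in \{1,\dots,8\}$ (time constants still tied per synapse label)
   and the lowest training error wins, ties going to the smaller $\rho$.
   With two multiplexed channels sharing one coupling, exact amplitude
   preservation is only possible for one channel; compensation uses
   channel 1's scale. The staged schedule itself only pretunes
   single-channel subunits, so the contract is exact where it is used.
3. **Decoupling.** Kernel parameters are freed per synapse group
   (typically proximal/middle/distal within a branch) and refined. When
   groups outnumber subunits, a log-normal prior guards against
   overfitting. Within a subunit the somatic amplitude $a_{ji}$ is
   proportional to $w_{ji}$ with a shared gain, so the prior is placed
   directly on $\log|w_{ji}|$ and $\log\tau_{ji}$, with means taken from
   the shared-kernel solution, log-SD `prior_sd = 0.5`, and weight
   `1/n_bins` (the scaling a Gaussian observation model with unit noise
   variance would give the penalty). With tens of seconds of data the
   data term dominates; the prior only disambiguates weakly constrained
   groups.

Because each stage starts from the previous stage's solution and the
optimizer keeps its best-seen iterate, training error is non-increasing
across stages, and a simpler nested model's training error is an upper
bound for the richer model fitted through this schedule.

Model quality is reported as variance explained,
$1 - \mathrm{MSE}/\mathrm{Var}(v)$ (population variance), on held-out
segments generated independently of the training data; the train/test
protocol follows the 10-segment, 48 s convention and both are exposed as
arguments.

## Spiking extension

Somatic spiking is added as an inhomogeneous Poisson process whose rate is
an exponential function of the subthreshold response,
$\lambda(t) = \lambda_0 e^{\beta \tilde v(t)}$. Output spikes feed back
additively into the root subunit's input through adaptation kernels: a
basis of $N_\Psi = 10$ raised-cosine bumps
$\psi_i(\tau) = \tfrac12[\cos(a \log(\tau + c) - \phi_i) + 1]$ on
$a\log(\tau+c) \in [\phi_i - \pi, \phi_i + \pi]$, with $a = 3.75$,
$c = 0.01$ and centres uniform on $[3, 22]$, weighted by coefficients
$\gamma_i$ (fitted jointly with the subthreshold parameters; they enter
the response linearly, so their gradients come free). **Units:** lag
$\tau$ is in milliseconds. With these constants the supports then tile
roughly 1 ms to 800 ms — the physiological range from fast after-spike
dynamics to slow adaptation; reading $\tau$ in seconds would instead put
them at 1–800 s, far outside any after-spike timescale, so the
millisecond reading is used and stated here explicitly. $(\lambda_0,
\beta)$ are fitted by maximising the Poisson log-likelihood
$\sum_{\text{spikes}} \log\lambda - \int \lambda\,dt$, which is concave
in $(\log\lambda_0, \beta)$, so BFGS from any start finds the optimum.
Spike generation uses per-bin thinning with at most one spike per bin at
`dt = 1` ms (emission probability $1 - e^{-\lambda\,dt}$); absolute
refractoriness is not modelled — suppression after a spike comes from the
adaptation kernels alone.

## The input generator

The generator emulates the synaptic bombardment of a sensory cortical
neuron during oriented-grating stimulation, with three ingredients:

* **Ensemble switching.** Excitatory synapses are divided into 13
  ensembles (defaults: 629 excitatory, 120 inhibitory synapses). Each
  ensemble switches synchronously between a background (5 Hz) and an
  elevated (20 Hz) rate. Switch-on is orientation tuned:
  $\Omega_{\mathrm{on}}(\Delta\theta) = \text{mid} + \text{half-range}
  \cdot \cos 2\Delta\theta$ anchored at 0.5–14 Hz, maximal at the
  ensemble's preferred orientation and minimal at the orthogonal one. The
  $\cos 2\Delta\theta$ form is the simplest sinusoid with the correct
  180° period on the orientation wheel and the two stated anchors; its
  phase is fixed by "maximum at preferred". Preferred orientations are
  drawn from Normal(0°, 33°) and rounded to the 16-orientation wheel
  (multiples of 22.5°). Switch-off is orientation independent at 20 Hz,
  and active states are capped at 150 ms — implemented by capping the
  exponential duration at the bound rather than resampling, so the cap
  also acts as an atom at 150 ms; durations never exceed it.
* **Slow rate fluctuations.** Within each ensemble the actual rate
  follows an Ornstein-Uhlenbeck process (exact discretisation) decaying
  toward the state-dependent equilibrium with $\tau = 500$ ms and
  stationary SD 2.5 Hz (background) / 10 Hz (elevated), shared by all
  synapses of the ensemble. The latent process is propagated unclipped;
  emitted rates are clipped at 0 Hz. At the default SDs the clipping
  bias is small (the elevated state sits 2 SD above zero; the censored
  SD is ≈ 9.8 Hz instead of 10) and the background state is essentially
  unaffected.
* **Poisson spiking and tracking inhibition.** Spikes are per-bin Poisson
  draws with mean rate × dt. Inhibitory synapses are untuned; their rate
  is an affine function of the instantaneous mean excitatory rate (the
  OU-fluctuating mean, not the equilibrium — "instantaneous" is read
  literally), mapping all-background to 20 Hz and all-elevated to 30 Hz.

A default session is one 3 s block of each of the 16 orientations (48 s);
every latent trace (states, rates, inhibitory rate) is returned for
testing. The generator is fully reproducible from one integer seed.

**What the generator does and does not emulate.** It reproduces the
switching statistics, within-ensemble correlations, slow rate
fluctuations and excitation-tracking inhibition of in-vivo-like input. It
does not place synapses on a morphology (ensemble membership is
metadata), does not model biophysical membrane dynamics, and produces
exactly Poisson spiking. Tests that pass against this generator therefore
validate the statistical machinery and the fitting pipeline, not the
model's adequacy for any particular recorded neuron.

## Evaluation statistics

Three summary statistics support calibration against dendritic
recordings: the plateau probability (fraction of time above −35 mV, the
conventional threshold for sustained NMDA-driven depolarisations), the
membrane-potential histogram (1 mV bins, normalised density), and the
autocorrelation decay timescale. The timescale estimator fits
$A e^{-\mathrm{lag}/\tau}$ to the (optionally segment-averaged) sample
autocorrelation by weighted least squares over lags up to `max_lag_ms`
(default 500 ms). Weights $e^{-2\,\mathrm{lag}/\tau_0}$, with $\tau_0$ a
pilot estimate from the 1/e crossing, approximate inverse relative
variance: sample-autocorrelation noise is roughly flat across lags while
the signal decays, and unweighted fits let the noisy tail dominate —
on 1,000 s of OU input at $\tau = 500$ ms the weighted estimator has
about half the spread of the unweighted one (±4% vs ±9% SD across
seeds).

## Numerical choices and limitations

* Problem sizes in the test suite: convolution oracles run on ≤ 2 s
  traces; fitting tests use 6-48 s of input from 10-100 synapses at
  `dt = 1` ms; generator statistics use 200-1,000 s of simulated rates.
  These sizes put every Monte-Carlo band well inside its tolerance while
  keeping the suite quick to run.
* BFGS tolerances default to `reltol = 1e-10`, `maxit = 250` per stage;
  the optimizer wrapper returns the best iterate seen, so a late
  line-search overshoot cannot degrade a stage.
* Ties across the $\rho$ grid are broken toward smaller $\rho$ (the more
  linear initialisation), which is the more conservative model.
* Degenerate inputs fail loudly: zero-variance subunit input during
  pretuning, zero-variance targets in variance explained, spikes outside
  the grid span, and unassigned synapses are all errors, not warnings.
* The architecture is supplied, not searched: candidate structures must
  come from the user, and model comparison is by held-out variance
  explained.
* The hLN family itself assumes instantaneous, static subunit
  nonlinearities and purely additive interactions between subunits;
  regenerative events with intrinsic dynamics (plateau onset/offset
  kinetics, spike backpropagation) are outside the model class, and the
  spiking extension predicts rate, not precise spike timing.

## A worked example

```{r example, eval = FALSE}
library(hlnd)

# synthesize a 48 s in-vivo-like session (scaled-down synapse counts)
cfg <- ensemble_config(n_ensembles = 4, n_exc = 80, n_inh = 20)
train <- generate_inputs(cfg, duration_s = 48, seed = 1)
test <- generate_inputs(cfg, duration_s = 48, seed = 2)

# a known single-subunit reference model provides the target voltage
teacher <- hln_single_subunit(train$synapses, v0 = -70)
g <- train$grid
v_train <- hln_forward(train$spikes, teacher, g)

fit <- fit_hln(
  train$spikes, v_train, teacher, g,
  test = list(list(
    spikes = test$spikes,
    voltage = hln_forward(test$spikes, teacher, g)
  ))
)
glance(fit)
autoplot(fit, train$spikes, v_train, window_s = c(0, 2))
```
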