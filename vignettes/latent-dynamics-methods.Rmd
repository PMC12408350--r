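---
title: "Inferring latent Langevin dynamics and tuning functions from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring latent Langevin dynamics and tuning functions from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedrift)
```

## The model

spikedrift treats the moment-to-moment state of a decision as a scalar latent
variable $x(t)$ on the domain $[-1, 1]$ obeying a Langevin equation

$$\dot x = D\,F(x) + \sqrt{2D}\,\xi(t), \qquad F(x) = -\Phi'(x),$$

with white noise $\xi$, noise magnitude $D$ (units $x^2/\mathrm{s}$) and a
potential $\Phi$ whose gradient supplies the deterministic force. Scaling the
drift by $D$ measures potential height in units of the noise, so the
equilibrium density $\propto e^{-\Phi}$ is invariant to $D$; the constant of
integration in $\Phi$ is fixed by $\int e^{-\Phi}dx = 1$, which makes
potentials comparable across models but leaves absolute offsets meaningless.
Each trial starts at $x_0 \sim p_0$ and ends the first time $x$ reaches a
boundary: the reaction time is a first-passage time, and $\pm 1$ are the two
choices. Neurons spike as inhomogeneous Poisson processes whose instantaneous
rates $f_i(x)$ read out the shared latent state; jointly the tuning functions
$f_i$ embed the one-dimensional dynamics in population rate space.

All functions live on a Chebyshev--Gauss--Lobatto grid (`build_grid()`), whose
endpoints coincide with the absorbing boundaries. One spectral cumulative-
integration matrix serves every integral in the package, so normalization and
reconstruction are mutually consistent to machine precision. The optimized
quantities are unconstrained auxiliary functions: the force $F^{(l)}$ per
condition, $F_0 = p_0'/p_0$, and per neuron $F_i = f_i'/f_i$ together with the
boundary rate $C_i = f_i(-1)$; exponentiating cumulative integrals guarantees
positivity and normalization by construction.

## Likelihood

The data of one trial are a marked point process: start time, sorted spikes
$(t_j, i_j)$, and the reaction time $t_E$. Between observations the latent
density obeys a modified Fokker--Planck equation whose generator combines
drift, diffusion and a decay term $\sum_i f_i(x)$ that removes probability at
the population rate -- the propagated density then weights only trajectories
that produced *no* spikes in the interval. Absorbing boundary conditions
remove trajectories that reach a boundary early, and a final boundary-flux
factor keeps only trajectories absorbed exactly at $t_E$. The trial likelihood
is the chain

$$p_0 \;\to\; \big[\text{ISI propagation} \to \text{emission } f_{i_j}\big]_j
\;\to\; \text{final propagation} \;\to\; \text{absorption},$$

evaluated as matrix--vector products with per-interval rescaling so products
over hundreds of spikes cannot underflow. Spikes are processed in continuous
time; simultaneous spikes are ordered by neuron index with a zero-length
interval. The propagator is applied exactly as $e^{-H\,\Delta t}$ through an
eigendecomposition of the interior generator, computed once per condition and
reused across a mini-batch; complex-pair eigenvalues are handled in complex
arithmetic and the result projected back to the reals. Boundary flux is read
from the one-sided spectral derivative at each boundary times $D$; tiny
negative densities from roundoff are clipped in sign only, never rescaled in
mass.

For comparisons that should not reward the reaction-time model (PSTH
baselines, population versus single-neuron contrasts), the full likelihood is
normalized by the likelihood of the reaction time alone -- the same chain with
no emissions and no decay term. The package conditions that factor on
reaching *either* boundary at $t_E$; conditioning on the reached boundary is
a one-line change in `trial_loglik()` callers because left and right fluxes
are returned separately by `absorb()`.

Gradients of the log-likelihood with respect to every component are computed
by an adjoint forward--backward pass in the eigenbasis. The derivative of
$e^{-H\Delta t}$ uses the divided-difference (Fr\'echet) form, which splits
into two rank-one accumulations per interval against a fixed per-batch matrix
of eigenvalue-difference reciprocals, so a whole mini-batch reduces to two
complex matrix products. The contract is equality with central finite
differences of the evaluated likelihood; the test suite verifies directional
agreement to about $10^{-6}$, well inside the $10^{-4}$ contract.

## Optimization

Fitting maximizes the summed log-likelihood with a functional variant of
ADAM. Function-valued components are scaled by the running average of the
squared $L^2$ norm of their gradient -- one scalar per function, not per node
-- while $D$ and $C_i$ use standard scalar ADAM with rectification at zero
(evaluation floors $D$ at $10^{-8}$ so a rectified optimizer state cannot
poison the generator). Defaults follow the reference protocol: learning rate
0.05 for single neurons (0.01--0.05 for populations), moments (0.9, 0.99),
$\epsilon = 10^{-8}$, 20 mini-batches per condition and epoch, 5000 epochs,
and 30 L-BFGS-B line searches on $(D, \{C_i\})$ spaced logarithmically over
the epochs. In shared optimization the batches of all conditions are pooled
and visited in random order; each condition's force is updated only on its
own batches, shared components on every batch. Initialization is the
maximally uninformative model inside the observed scale: zero force, uniform
$p_0$, constant tuning at each neuron's empirical mean rate, $D = 0.1$.

Two numerical choices matter and are deliberate:

* **Smooth functional subspace.** The likelihood has almost no curvature
  along node-scale oscillations of $F$, $F_0$, $F_i$ -- the inverse problem is
  ill-posed at the grid scale -- so norm-scaled updates would execute a random
  walk there and the force estimate degenerates into discretization noise.
  Functional gradients are therefore projected onto the leading Chebyshev
  modes before each update (`n_modes`, default 16). This is the package's
  analogue of representing the optimized functions spectrally; it bounds the
  spatial frequency of learnable features at about `2/n_modes` in $x$, which
  is far finer than the potential structure the model class targets.

* **Reflection gauge.** The likelihood is exactly invariant under $x \to -x$
  (both boundaries are collected by the absorption factor), so each finished
  fit is oriented by the behavioural convention that the right boundary is
  the right choice, using the model's per-trial absorption split on the
  choice-labelled training trials. Without gauge fixing, independent fits of
  the two data halves can converge to mirrored solutions and consistency
  comparisons report spurious disagreement.

## Model selection by feature consistency

Optimization produces a trajectory of models that first acquires true
structure and later overfits; held-out likelihood cannot reliably separate
the two regimes for flexible models. The package instead measures the
*feature complexity* of each snapshot -- the negative trajectory entropy
relative to free diffusion in a constant potential,

$$\mathcal{M} = \mathrm{KL}(p_0\,\|\,\mathrm{uniform}) +
\frac{D}{4}\int_0^\infty\!\!dt\int dx\, F^2(x)\,p(x,t),$$

with the time integral evaluated in closed form as $H^{-1}p_0$ (every
eigenvalue of the absorbing generator has positive real part) -- and compares
models of matched complexity fitted independently to the even- and odd-
indexed trials. Consistency is a Jensen--Shannon divergence between the two
models' latent dynamics; the selected model pair is the last one whose
divergence stays below the threshold 0.0015 before the divergence leaves the
band for `patience = 3` consecutive pairs. Scanning upward in complexity and
requiring persistence makes the rule robust to two artefacts seen in
practice: isolated noise spikes of the divergence at low complexity, and
degenerate high-complexity regimes where two pathologically overfit models
(near-instant absorption) look deceptively similar.

The divergence itself is computed, by default, between the models' expected
occupancy measures $\int_0^\infty p(x,t)\,dt$, normalized over $x$. The
occupancy integrates the full time course of the first-passage dynamics,
varies smoothly along the optimization path, and grows cleanly as spurious
features appear, crossing the fixed threshold at the onset of overfitting in
synthetic-recovery experiments; the joint density over $(x, t)$ on a common
time window is available as `method = "joint"` and behaves more noisily at
equal fit quality. The choice of measure was validated exactly the way the
selection procedure itself prescribes: on synthetic data with known ground
truth, the selected models must reproduce the generating potential.

Fit outcomes are classified as in the reference analysis: `overfit`
(unphysiological tuning peaks together with pathological $D$ or potential
depth -- healthy fits sit near $D \sim 0.2$--$0.6$ and depth $\sim 2$),
`underfit_no_signal` (potential tilts to the same boundary in every
condition), `underfit_split_disagreement` (halves tilt oppositely in some
condition), else `good`. Barrier counting uses the two selected force
estimates: a sign change counts when both halves hold the pre-change sign
over a run of nodes on one side of a local region and the post-change sign on
the other, ignoring changes close to the boundaries. The run length is a node
count (10 of 256, scaled with the grid, at least 2); the boundary margin is
defined by *extent* -- the nodes within 30/255 of the domain length of each
boundary -- because on a boundary-clustered grid a fixed node count would
exclude a far narrower slice of the domain than the rule intends.

Uncertainty bands come from a bootstrap: trials are first split into two
fixed non-overlapping halves, each bootstrap sample resamples trials with
replacement within each half (per condition), the full fit-and-select
procedure is rerun, and bands are pointwise standard deviations across the
$2 \times n_\mathrm{boot}$ selected models.

## Single-trial validation

`viterbi_path()` generalizes max-sum Viterbi decoding to the continuous-state
continuous-time model: grid-valued states at the trial's event times, inter-
event transition kernels from the spike-decay propagator, and a terminal
absorption factor that forces the decoded trajectory onto a boundary at
$t_E$. On an exact terminal tie the boundary on the side of the best terminal
interior state is taken. Dense paths interpolate linearly between event-time
states; this piecewise-linear rule replaces a kernel-bridge interpolation
because every downstream consumer (rates at spike times, choice prediction)
only needs values between events at scales where the two agree.

Spike-time $R^2$ measures the fraction of single-trial spike-time variation a
rate prediction explains: total variation is the squared coefficient of
variation of raw ISIs, residual variation the CV$^2$ of ISIs after rescaling
time by the predicted cumulative rate (trapezoidal rule), and
$R^2 = 1 - \mathrm{CV}^2_\mathrm{residual}/\mathrm{CV}^2_\mathrm{total}$,
analysed per condition and averaged. A constant prediction gives exactly
zero; the true rate reduces the residual variation to the point-process
variability, which for Poisson spiking is unity in operational time. The
independent estimator of that point-process variability, $\phi$, solves a
quadratic in spike-count means and variances at bin sizes $T$ and $2T$; both
roots are reported and the admissible root in $(0, 2]$ closest to the plug-in
ISI CV$^2$ is returned (exact Poisson moments give roots $\{1, 4\mu - 1\}$
and $\phi = 1$). The bin size is exposed because the identity holds for any
$T$ large enough for stable moments; the tests use 50 ms.

Choice prediction reads the boundary of the decoded path; accuracy is
balanced (mean of the per-class hit rates) because error trials are rare.
The baseline decoder is a ridge-regularized logistic classifier on spike
counts in 75-ms windows sliding in 10-ms steps over the first 0.5 s (42
windows per neuron), z-scored per condition and window with training-fold
statistics, cross-validated over the same two data halves as the model;
conditions lacking five errors in either half are excluded. Leave-one-neuron-
out validation decodes the path from all other neurons, predicts the held-out
neuron's rate through its tuning curve, interpolates with a cubic spline to
its spike times and scores with the inhomogeneous-Poisson likelihood. Unit
filters mirror the reference criteria: choice-sorted PSTH reaching 15 Hz
before the median reaction time, at least 560 trials, and a choice
selectivity (ROC area of spike counts in the 0.2--0.35 s window) above 0.6.

## Synthetic data

The Langevin generator is the model's own generative process:
Euler--Maruyama steps (default $dt = 5\times10^{-4}$ s) with two absorption
tests per step -- endpoint crossing located by a linear bridge, and a
Brownian-bridge test for within-step excursions. The second test matters:
without it first-passage times are biased long by $O(\sqrt{dt})$, and at a
few hundred trials per condition that bias is large enough to tilt fitted
forces near the rarely-visited error boundary. With it, simulated mean
first-passage times match the closed form for pure diffusion to a fraction
of a percent. A residual $O(dt)$ bias remains (the bridge ignores drift), so
recovery experiments simulate at $dt = 1.5\times10^{-4}$ s.

The ground-truth library uses inverted-parabola potentials -- linear force
$k(x - x^\ast)$ with the barrier top $x^\ast$ displaced away from the correct
boundary -- so each trial is a noisy escape from near the barrier top and the
force crosses zero exactly once. Defaults were chosen once for task realism:
$k = 7$, displacements 0.3 (easy) and 0.15 (hard), $D = 0.4$, a narrow
Gaussian initial density ($\sigma = 0.14$) at the centre, and two
opposite-preference sigmoid tuning curves spanning roughly 5--45 Hz. Under
these settings simulated behaviour shows median reaction times near 0.4--0.6
s and accuracies near 80% (easy) and 60--65% (hard), with error trials that
cross the barrier -- the regime the method is meant for. What the generator
does not emulate: non-Poisson spike irregularity, slow non-stationarities
across trials, neurons driven by variables other than the shared latent
state, and spike-sorting artefacts; passing recovery tests therefore
demonstrates correctness of the inference machinery, not robustness to every
property of real recordings.

The attractor-network generators provide dynamics *outside* the fitted model
class. The two-pool mean-field reduction uses the printed parameters
($\gamma = 0.641$, $\tau_s = 100$ ms, $a = 270$ Hz/nA, $b = 108$ Hz,
$d = 0.154$ s, $J_{11} = 0.2609$, $J_{12} = -0.0497$, $I_{bg} = 0.3260$,
stimulus coefficient 0.0208 nA, coherence presets $\pm 0.175$ and
$\pm 0.075$), Ornstein--Uhlenbeck noise on the input currents (2 ms, 0.02 nA
-- white current noise has no $dt$-independent meaning through the memoryless
transfer function), Poisson spikes from the pool rates, and a reaction time
at the first crossing of 30 Hz by a 200-ms moving-average rate. At zero
coherence the flow has two symmetry-broken attractors and a saddle whose
stable manifold is the diagonal. The rank-two network $\dot y = -y + [Jy+b]_+$
replicates that flow with distributed connectivity: cosine/sine loadings,
ridge-regressed readout ($\lambda = 0.01$), and input offsets uniform on
$[-0.6, 0.6]$. The offset range is the one deliberate departure from the
printed description (0.06): the offsets place the rectification kinks of the
units, and at a tenth of the range every kink crowds one corner of the state
space, leaving the regression unable to reproduce the flow's curvature at any
sample size (held-out residual near 40% instead of below 3%). Trajectories
from the near-symmetric starts $(0.12, 0.106)$ and its swap are parametrized
by cumulative arc length into a decision variable on $[-1, 1]$, and each
unit's rate along the trajectories is its tuning curve -- the construction
that shows how diverse tuning arises from low-dimensional dynamics through
the firing-rate nonlinearity.

## Problem sizes and degenerate inputs

The shipped experiments run on one CPU at deliberately modest scale, chosen
as package defaults: recovery fits use a 48-node grid, 500 trials per
condition in four conditions with two neurons, 400 epochs at learning rate
0.03 with an 8-mode functional basis, and 6 line searches. At these sizes a
two-split fit takes a few minutes and recovers potentials with correlation
above 0.9, tuning above 0.98, and a single counted barrier in every
condition. Grids below 8 nodes are rejected (no meaningful second-derivative
operator); empty conditions, spikes outside the trial window, out-of-range
neuron indices and negative rates are rejected with explicit errors;
likelihoods of impossible data (for example a spike from a silenced neuron)
are $-\infty$ rather than errors.

## Known limitations

The latent space is one-dimensional by design. Emission is Poisson
conditional on the latent state; more regular interval statistics appear in
validation only through the $\phi$ estimator, not inside the likelihood.
Selection inherits the premise that split-consistency rises monotonically at
the onset of overfitting; the persistence rule guards against noise but a
pathological divergence curve can still end the scan early, which surfaces as
an `underfit` outcome label rather than silently. Bootstrap bands are
pointwise standard deviations, not calibrated confidence intervals.
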