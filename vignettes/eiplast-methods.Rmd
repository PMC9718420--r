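---
title: "Stabilizing Hebbian plasticity with a nonlinear inhibitory rule: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilizing Hebbian plasticity with a nonlinear inhibitory rule: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiplast)
```

## The circuit and its rate dynamics

`eiplast` models a feedforward inhibitory motif: a single postsynaptic
excitatory neuron receives input from $N^E$ presynaptic excitatory neurons
firing at rate $\rho^E$ through a plastic weight $w^{EE}$, and from $N^I$
inhibitory neurons firing at $\nu^I$ through a plastic weight $w^{EI}$. The
inhibitory neurons are driven by the same presynaptic pool (fixed weight
$w^{IE}$) and an external drive $\rho^I$. Rates follow threshold-linear
dynamics,

$$\tau_{FR}^E \dot\nu^E = -\nu^E + \left[N^E\rho^E w^{EE} -
  N^I\nu^I w^{EI} + \rho_{add}\right]_+,\qquad
  \tau_{FR}^I \dot\nu^I = -\nu^I + \left[N^E\rho^E w^{IE} + \rho^I\right]_+,$$

where $[\cdot]_+$ rectifies negative values to zero. In the mean-field
reading all variables are population means and $N^E = N^I = 1$ at the
standard working point; the counts remain explicit parameters so that the
stability condition below can be swept in them.

Three plasticity rules act on the weights. Excitatory synapses follow a
Hebbian rule that is nonlinear in the postsynaptic rate,

$$\tau_w^E\,\dot w^{EE} = \rho^E \nu^E (\nu^E - c_{post}^E),$$

switching from depression (LTD) to potentiation (LTP) at the postsynaptic
threshold $c_{post}^E$. For inhibitory synapses the package implements both
the classical linear rule
$\tau_w^I \dot w^{EI} = \nu^I(\nu^E - c_{post}^I)$ and the nonlinear rule

$$\tau_w^I\,\dot w^{EI} = \nu^I \nu^E (\nu^E - c_{post}^I),$$

whose two defining features are that inhibitory weights change with the
*same sign* as excitatory ones and that no inhibitory plasticity occurs
while the postsynaptic neuron is silent. $c_{post}^I$ is the target rate:
at $\nu^E = c_{post}^I$ all plasticity stops.

## Closed-form theory

With equal thresholds $c_{post}^E = c_{post}^I = c_{post}$ the two
nullclines coincide in a line of fixed points,
$w^{EI} = \frac{N^E\rho^E}{N^I\nu^I} w^{EE} - \frac{c_{post}}{N^I\nu^I}$
(`line_attractor()`), valid where the postsynaptic rate is positive; the
zero-rate boundary through the origin shares its slope. On the attractor
the Jacobian of the coupled weight dynamics has determinant zero and
eigenvalues $\{\mathrm{Tr}(J^*), 0\}$ with

$$\mathrm{Tr}(J^*) = \left(\frac{N^E(\rho^E)^2}{\tau_w^E} -
  \frac{N^I(\nu^I)^2}{\tau_w^I}\right) c_{post},$$

so the line is attracting exactly when inhibition dominates,
$N^I(\nu^I)^2/\tau_w^I > N^E(\rho^E)^2/\tau_w^E$
(`stability_condition()`; `jacobian_numeric()` provides an independent
finite-difference check). Under the linear inhibitory rule stability
instead depends on the initial weights, with the separatrix
$w^{EI} = \frac{N^E\rho^E}{N^I\nu^I}w^{EE} -
\frac{\nu^I\tau_w^E}{N^E(\rho^E)^2\tau_w^I}$ dividing convergent from
runaway initializations (`separatrix_linear_rule()`).

The steady-state excitatory-to-inhibitory weight ratio
$R^{E/I} = w^{EE}/w^{EI}$ approaches
$R^{E/I}_\infty = N^I\nu^I/(N^E\rho^E)$ for strong inhibitory weights, the
reciprocal of the attractor slope in the $(w^{EE}, w^{EI})$ plane; for
$N^E = N^I$ and large $\rho^E$ it is bounded below by $w^{IE}$
(`ei_ratios()`). The presynaptic LTD/LTP threshold — the presynaptic rate
at which excitatory plasticity changes sign —
is $c_{pre}^E = (c_{post} + N^I\nu^I w^{EI})/(N^E w^{EE})$
(`presynaptic_threshold()`; a self-consistent variant that lets $\nu^I$
track $\rho^E$ is provided for plotting threshold curves against the input
rate).

## Time units, the Euler step, and the instantaneous-rate mode

Rate-model constants of this kind are conventionally quoted in mixed units
(rate time constants in seconds next to a dimensionless Euler step of 0.1).
The package avoids the ambiguity by treating *all* times as one consistent
arbitrary unit and documents two regimes:

* **Single-neuron experiments** default to `dt = 0.01` with
  `tau_FR = dt` — the *instantaneous-rate* mode, in which one Euler step
  lands exactly on the rectified steady state. The rate update is ordered
  upstream-first (inhibitory population, then postsynaptic neuron) so that
  this degeneracy is exact. `step_rates()` rejects `dt > tau_FR`, the
  explicit-Euler stability bound. A step of 0.1 is *not* used as the
  default because, combined with instantaneous rates, it overshoots the
  absorbing $\nu^E = 0$ region from the standard initialization
  $[w^{EE}_0, w^{EI}_0] = [2.5, 1]$ and freezes the run, whereas the
  continuous-time trajectory converges to the attractor.
* **Circuit experiments** (receptive fields, recurrent network) use
  `dt = 1e-4` with instantaneous integrators, matching the faster rate
  constants quoted for that configuration.

Update order within a step: evaluate the drive, update rates, evaluate the
plasticity rules at the *updated* rates, update weights and thresholds.
Weights are floored (default 0) after each step; divergence is detected by
a guard (default $10^6$ weight units, plus NaN detection) and reported as a
flag with the blow-up time rather than an error. "At steady state" is
operationalized as $\max(|\dot w^{EE}|, |\dot w^{EI}|) < 10^{-8}$ per unit
time.

## Sliding thresholds (metaplasticity)

With unequal thresholds the attractor disappears: for
$c_{post}^E < c_{post}^I$ rates stabilize but both weights grow without
bound, and for $c_{post}^E > c_{post}^I$ both shrink. The dynamic-threshold
mechanism couples the thresholds to the realized plasticity,

$$\tau_c\,\dot c_{post}^E = \dot w^{EE}, \qquad
  \tau_c\,\dot c_{post}^I = -\dot w^{EI},$$

so the two slide toward each other and the rate settles at the common
matched value. Two numerical choices matter here:

* **`tau_c` defaults to 2.** The threshold timescale is nominally 2 ms;
  read in the millisecond time base (the one that also reconciles a 0.1
  step with 10-ms rate constants) this is 2 simulation time units. The
  alternative reading (0.002) makes the thresholds slide
  ~500× faster than the weights; the inhibitory threshold then outruns the
  decaying rate during the initial transient and both thresholds collapse
  onto the positivity clamp ($10^{-6}$ Hz) with a dead network — the
  opposite of the matching behavior the mechanism is meant to produce.
  With `tau_c = 2` the thresholds from $(0.7, 1.3)$ and $(1.3, 0.7)$ meet
  at intermediate rates and weights and rates stabilize.
* **Initial weights $[1, 1]$ for the matching demonstration.** Matching
  requires the weights to stay strictly above the zero floor: while the
  thresholds are unequal the weights drift monotonically (down for
  $c_{post}^E > c_{post}^I$), and from $[1.5, 0.5]$ they reach the floor
  before the thresholds meet, which freezes the circuit. $[1, 1]$ keeps
  both weights alive through the transient in either threshold ordering.

## Drives, noise, and drift statistics

`drive_spec()` modulates one of $\rho^E$, $\rho_{add}$, $\rho^I$ as a
constant, an instantaneous permanent step, per-step i.i.d. Gaussian noise,
or a sinusoid. Noise is added per Euler step *without* $\sqrt{dt}$
scaling, mirroring the per-step construction of the model; its effective
intensity therefore depends on the step, and the documented noise
experiments run at the model's own step of 0.1. Additive postsynaptic variability shifts only
the attractor's intercept ($\rho_{add}$ enters the numerator of the
intercept), so weights stay within a band; varying $\rho^E$ tilts the
attractor's slope and produces a slow ratcheting drift of both weights —
reproduced by `varying_drive_experiment()`, which reports ordinary
least-squares drift slopes over the final half of the recorded samples
together with the rate mean and variance. The drift statistic is a package
choice; the source describes the drift only qualitatively.

## Receptive-field and recurrent-assembly experiments

The multi-input circuit (`run_multi_input()`) has 10 input patterns of 4
presynaptic neurons each (40 in total); in every 100-ms window one pattern
fires at 4 Hz against a 1-Hz background. Ten input-specific inhibitory
populations (2 neurons each, $w^{IE}_{spec} = 0.2$, each wired only to its
own pattern) and one unspecific population (20 neurons,
$w^{IE}_{unsp} = 0.02$, wired to all 40 inputs) inhibit the postsynaptic
neuron; all feedforward E-to-E and I-to-E weights are plastic (nonlinear
rule). Disinhibition applies an external drive of $-2$ to one inhibitory
class for 60 s (entering before the rectifier, so $\nu^I \ge 0$); for the
specific class its release is a linear ramp over 100 s, the simplest
implementation of a slow, gradual release that avoids silencing the
postsynaptic neurons. Disinhibiting the specific populations removes the
input-specific cancellation of excitatory plasticity and lets one input win
(receptive-field formation); disinhibiting the unspecific population leaves
the specific loops intact and no competition arises.

The recurrent experiment (`run_recurrent()`) gives each of 30 such circuits
a plastic all-to-all recurrent weight matrix (partner rate in place of the
input rate in the excitatory rule, one-step transmission delay) plus weak
feedback connections from the excitatory neurons onto their inhibitory
populations (0.002 specific / 0.001 unspecific, a mild feedback-motif
stabilizer). Four recurrent-layer choices are deliberate package
decisions, each exposed as a parameter:

* **Initial recurrent weights $U[0, 0.018]$.** A range ten times wider,
  $U[0, 0.18]$, gives the all-to-all network a recurrent gain of
  $29 \times 0.09 \approx 2.6 > 1$, so the threshold-linear rates diverge
  within a few steps before any plasticity can act — and it would also put
  half of the *initial* weights above the 0.03 display threshold used for
  reporting connectivity.
* **`tau_w_rec = 10`.** The inhibitory-dominance margin at the circuit's
  constants is thin (inhibitory growth coefficient ≈ 122 Hz² vs. a
  feedforward excitatory coefficient of 100 Hz²); recurrent plasticity at
  the feedforward timescale adds ≈ $29\nu^2$ to the excitatory side and
  tips every active state into runaway. Slower recurrent potentiation
  preserves dominance while still letting assemblies form.
* **`w_rec_max = 0.1`.** Recurrent weights between co-tuned neurons see
  correlated pre- and postsynaptic activity that input-specific inhibition
  does not cancel, so they ratchet upward until an assembly's recurrent
  gain exceeds one; the upper bound caps that gain.
* **`pattern_correlation = 0.5`.** Each neuron follows the shared pattern
  sequence with probability 0.5 and an independent draw otherwise. Fully
  shared sequences with identical initial feedforward weights are exactly
  symmetric: all 30 neurons then acquire the *same* preferred input and a
  single all-to-all assembly, leaving no across-preference pairs at all.
  Partial correlation breaks the symmetry while keeping co-tuned neurons
  co-active.

The recurrent structure is sharpest at the end of the disinhibition
window; the slow release partially erodes it (inhibition is still partly
withdrawn early in the ramp, so potentiation there is undifferentiated,
and a few neurons can lose their receptive field entirely), but the
within-preference vs. across-preference ordering of recurrent weights
survives the full protocol, which is what the reported
`analyze_selectivity()` statistics (selectivity index, group means,
bidirectionality score $\min(w_{ij}, w_{ji})$) measure.

## What the generators emulate — and what they do not

All inputs are synthetic: constant mean-field rates, i.i.d. per-step
Gaussian fluctuations, deterministic sinusoids, and uniformly random
pattern sequences. These reproduce the stationary statistics the theory is
written for, but real spike trains have Poisson-scale variance, temporal
correlations, and adapting rates that none of the drives emulate; the
mean-field collapse also ignores heterogeneity across synapses and
neurons. Passing tests therefore validate the weight-dynamics theory and
its circuit-level consequences, not quantitative agreement with recorded
biological data.

## Problem sizes and tolerances

The test suite integrates single-neuron runs for $10^2$–$10^5$ steps and
circuit runs for $1.7\times10^6$ steps (30 neurons, 40 inputs), sizes at
which every qualitative regime of the model (convergence, runaway,
threshold matching, drift, receptive-field formation, assembly growth) is
expressed; the compiled core makes the full suite run in well under a
minute. Key tolerances: attractor membership and convergence of terminal
rates to the target, $10^{-3}$; eigenvalue and determinant agreement
between the closed form and the central-difference Jacobian (step
$10^{-6}$), $10^{-6}$; steady state, $\max|\dot w| < 10^{-8}$ per unit
time. Ties in the preferred-input argmax break to the lowest input index;
thresholds are clamped at $10^{-6}$ Hz; the divergence guard is $10^6$.

## Known limitations

* Explicit Euler with per-step noise makes stochastic runs step-size
  dependent by construction; results are reported at the documented steps.
* The feedback-motif inhibitory equation and the recurrent-layer
  constants are package design choices (documented above), selected for
  dynamical consistency rather than derived from data.
* The dynamic-threshold mechanism is non-local (one threshold pair per
  neuron) and fails when weights reach the zero floor; both properties are
  inherited from the model.
* No spiking, conductance, or multi-compartment biophysics; no fitting to
  experimental recordings.
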