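# eiplast

Hebbian plasticity of excitatory-to-excitatory synapses is unstable on its
own: potentiation raises the postsynaptic rate, which drives further
potentiation. `eiplast` is an R package for simulating and analysing a
circuit-level solution to this runaway problem: **plasticity of
inhibitory-to-excitatory synapses that depends nonlinearly on the
postsynaptic rate**, so that inhibitory weights potentiate and depress with
the *same sign* as excitatory weights and change not at all while the
postsynaptic neuron is silent. It is aimed at computational neuroscientists
studying firing-rate homeostasis, excitation/inhibition balance, and
disinhibition-gated learning in rate-based circuit models.

## The model

A threshold-linear postsynaptic neuron receives excitation from $N^E$
presynaptic neurons (rate $\rho^E$, plastic weight $w^{EE}$) and inhibition
from $N^I$ inhibitory neurons (rate $\nu^I$, plastic weight $w^{EI}$):

$$\tau_{FR}^E\,\dot\nu^E = -\nu^E + \left[N^E \rho^E w^{EE} - N^I \nu^I w^{EI}\right]_+$$

with the inhibitory population driven by the same inputs through a fixed
weight $w^{IE}$ plus an external drive $\rho^I$. The weights evolve as

$$\tau_w^E\,\dot w^{EE} = \rho^E\,\nu^E(\nu^E - c_{post}^E), \qquad
  \tau_w^I\,\dot w^{EI} = \nu^I\,\nu^E(\nu^E - c_{post}^I),$$

where $c_{post}$ is the LTD/LTP threshold (the target rate). With equal
thresholds the coupled weight dynamics possess a **line attractor**
$w^{EI} = \frac{N^E\rho^E}{N^I\nu^I}\,w^{EE} - \frac{c_{post}}{N^I\nu^I}$,
stable exactly when inhibition dominates:
$N^I(\nu^I)^2/\tau_w^I > N^E(\rho^E)^2/\tau_w^E$. On the attractor the
neuron fires at the target rate, the E/I weight ratio is pinned near
$R^{E/I}_\infty = N^I\nu^I/(N^E\rho^E)$, and plasticity is "off" until a
perturbation — an input-rate step, added noise, or disinhibition — gates it
back "on". The package implements the simulations (compiled Euler core),
the closed-form phase-plane theory (attractor, separatrix of the classical
linear rule, Jacobian spectrum, E/I ratios, presynaptic thresholds),
sliding metaplastic thresholds, and the multi-input / 30-neuron recurrent
circuits in which disinhibition gates receptive-field and assembly
formation.

## Worked example

```r
library(eiplast)
p  <- ff_params()           # rho_E = 2 Hz, rho_I = 0.5 Hz, w_IE = 0.5
pl <- plasticity_params()   # nonlinear rule, c_post = 1 Hz, tau_w = 1 / 0.2

run_to_convergence(p, pl, weight_state(1.5, 0.5))
#> E/I plasticity trajectory: 6 recorded steps over t in [0, 2.64]
#>   rule: nonlinear inhibitory plasticity
#>   final: w_EE = 1.845, w_EI = 1.793, nu_E = 1 Hz, nu_I = 1.5 Hz (converged at t = 2.64)

stability_condition(p, pl)
#> inhibitory dominance: N_I nu_I^2 / tau_w_I = 11.25 > N_E rho_E^2 / tau_w_E = 4
#>   => stable line attractor; Tr(J*) = -7.25, Det(J*) = 0, eigenvalues {-7.25, 0}

line_attractor(p, c_post = 1)
#> attractor line: w_EI = 1.33333 * w_EE -0.666667  (crosses w_EI = 0 at w_EE = 0.5)

perturbation_experiment(p, pl, rho_base = 2, rho_disr = 2.5)
#> presynaptic rate step 2 -> 2.5 Hz
#>   nu_E: 1 -> 1 Hz (target 1); nu_I: 1.5 -> 1.75 Hz
#>   w_EE: 1.845 -> 1.976; w_EI: 1.793 -> 2.251
#>   presynaptic LTD/LTP threshold c_pre_E: 2 -> 2.5 Hz
```

Reading the output: the weights converge onto the line attractor
(`1.793 = 1.333·1.845 − 0.667`) with the postsynaptic rate at the 1-Hz
target; the dominance inequality (11.25 > 4) is why the attractor is
stable, with one contracting eigenvalue (−7.25) and one neutral direction
along the line. After a permanent input step both weights potentiate, the
rate returns to target, and the presynaptic LTD/LTP threshold shifts to the
new input rate — a metaplastic change carried entirely by inhibition.

Circuit-level experiments follow the same pattern:
`run_multi_input(multi_input_params(), "specific")` forms a receptive field
under specific-population disinhibition, and `run_recurrent()` grows
bidirectional assemblies among co-tuned neurons in the 30-neuron recurrent
network. A command-line front end (`inst/cli/eiplast.R`) exposes the
experiments as subcommands with YAML configs, seeded RNG, and CSV/JSON
outputs; see the methods vignette (`vignettes/eiplast-methods.Rmd`) for the
model's assumptions, parameter choices, and numerical details.

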