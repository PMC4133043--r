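---
title: "A two-layer spiking model of perceptual learning through feedback shunting inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer spiking model of perceptual learning through feedback shunting inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Perceptual learning of orientation discrimination changes the response
properties of neurons in primary visual cortex (V1) without moving their
preferred orientations: some studies find *sharpened* tuning curves, others
find *reduced* responses to the trained orientation, and in both cases the
orientation map is preserved. `shuntlearn` implements a spiking-network
account in which those changes are produced not by plasticity of local V1
circuitry but by learned **top-down feedback** from a higher area (V2).
Training strengthens feedforward V1→V2 synapses (Hebbian), the resulting
extra V2 drive strengthens diffuse excitatory feedback V2→V1
(homeostatic), and because that feedback excites V1 inhibitory cells along
with excitatory ones, its net effect is **shunting inhibition**: balanced
excitatory and inhibitory currents that cancel at rest, lower the input
resistance, and *subtract* from stimulus-evoked responses. Reduction and
sharpening then emerge in different neurons of the same network, and
orientation preference never moves because the feedback is untuned in
space.

## The model

### Neurons

Single-compartment Hodgkin–Huxley neurons (capacitance 1, per-unit-area
conductances):

$$\dot V = g_L(V_L - V) + g_{Na}m^3h(V_{Na} - V) + g_K n^4(V_K - V) +
g_{Ca}\,m_{Ca,\infty}^2(V)(V_{Ca} - V) + g_{AHP}[Ca](V_K - V) + I_{syn} + I_{inj}$$

with standard first-order gate kinetics $\dot x = \alpha_x(V)(1-x) -
\beta_x(V)x$ for $x \in \{m,h,n\}$. Parameters: $g_{Le} = 0.05$ (excitatory)
/ $g_{Li} = 0.1$ (inhibitory, hence a twice-faster membrane), $g_{Na} =
100$, $g_K = 40$, $g_{Ca} = 0.9$, $g_{AHP} = 0.05$ (excitatory only),
$V_L = -65$, $V_{Na} = 55$, $V_K = -80$, $V_{Ca} = 120$ mV,
$\tau_{Ca} = 100$ ms.

The rate functions are a Traub–Miles-style regular-spiking set:

* $\alpha_m = 1.28\,\phi((V+48)/4)$, $\beta_m = 1.4\,\phi(-(V+21)/5)$
* $\alpha_h = 0.128\,e^{-(V+44)/18}$, $\beta_h = 4/(1+e^{-(V+21)/5})$
* $\alpha_n = 0.16\,\phi((V+52)/5)$, $\beta_n = 0.5\,e^{-(V+57)/40}$

with $\phi(x) = x/(1-e^{-x})$. Relative to the classical forms the sodium
gates are shifted 6 mV depolarized: with the small leak conductance used
here the classical sodium window current exceeds the leak near −65 mV and
no stable resting state exists; the shift restores a quiet rest at
−64.9 mV while keeping regular spiking with spike-frequency adaptation
(via the calcium-dependent after-hyperpolarization current $I_{AHP}$,
absent in inhibitory cells). The high-threshold calcium channel activation
is $m_{Ca,\infty} = 1/(1+e^{-(V+20)/9})$.

Intracellular calcium is the model's activity variable (arbitrary units):
it decays with $\tau_{Ca} = 100$ ms and jumps by `ca_inc` (default 0.2) at
every spike, detected as an upward crossing of 0 mV with a 2 ms refractory
window. Calcium drives both $I_{AHP}$ and the two learning rules.

### Synapses

AMPA (excitatory) and GABAa (inhibitory) gating variables decay with
$\tau = 2$ ms and jump by 1 at each presynaptic spike. Currents follow
$I = g\,s\,(E - V)$ with $V_{ee} = V_{ei} = 0$ mV and $V_{ie} = -80$ mV.
The printed magnitude "80" for the inhibitory reversal is implemented as
−80 mV: a positive GABAa reversal would be excitatory and could not
produce the balanced cancellation at rest that defines the model's
mechanism. Depression factors $f_e, f_i$ exist in the current equations
but are fixed at 1 (no short-term plasticity dynamics are part of this
model).

### Architecture

* V1: 100 excitatory + 25 inhibitory neurons on a ring tiling 180° of
  orientation (1.8°/neuron); inhibitory neurons interleave at one per four
  excitatory cells, at interval midpoints. V2: 100 excitatory neurons, no
  V2 recurrence, no V2 inhibition.
* Recurrent V1 weights (E→E, E→I, I→E) are deterministic Gaussians of
  ring distance (s.d. 10 neurons); they never learn. E→E autapses are
  excluded. There is no I→I coupling by default (configurable).
* Feedforward V1E→V2 connections exist with Bernoulli probability
  `ff_p_peak` · Gaussian(distance; s.d. 5 neurons) — a compact, convergent
  projection — with a uniform initial magnitude. The sparsity pattern is
  frozen; only magnitudes learn.
* Feedback: one scalar weight per V2 neuron, fanning out *uniformly* to
  every V1 neuron; onto inhibitory cells it is scaled by `fb_to_i`
  (default 3, see below).

The ring (circular) topology is the default because orientation is
periodic; a bounded variant exists for edge-effect studies.

### Plasticity

With $[Ca]_j^{V1}$, $[Ca]_i^{V2}$ the calcium concentrations:

* Feedforward (Hebbian): $\dot W_{ij} = \eta_{hebb}\,
  [Ca]_j^{V1}[Ca]_i^{V2} / \tau_{Hebb}$, $\tau_{Hebb} = 100$ ms, clipped
  at a hard ceiling. Pure growth — the ceiling is what bounds it.
* Feedback (homeostatic): $\dot w_i = \eta_{fb}\,([Ca]_i^{V2} -
  [Ca]_{0,i}) / \tau_{FB}$, $\tau_{FB} = 500$ ms, clipped to
  $[0, w_{max}]$. Above-set-point V2 activity strengthens feedback, which
  (through the balanced E/I recruitment) suppresses V1 and hence V2 — a
  stabilizing loop.

**The set-point is per neuron**: $[Ca]_{0,i}$ is V2 neuron $i$'s own
time-averaged calcium during a pre-training baseline presentation of the
training stimulus, computed once and frozen. A single population-wide
scalar target was rejected for two reasons: it drags the feedback weights
of V2 neurons outside the trained population to zero (so a far test
stimulus would evoke *less* feedback than in the naive network, contrary
to the flat far-stimulus feedback profile the model is meant to show), and
it cannot restore the population-average calcium after training. With
per-neuron targets, silent neurons sit exactly at their set-point and keep
their naive weights, and homeostatic closure returns every trained
neuron — hence the population — to its baseline.

Because calcium units are arbitrary, the printed $1/\tau$ factors alone do
not fix how much weight change one presentation produces; the dimensionless
gains $\eta_{hebb}$ (default 0.001) and $\eta_{fb}$ (default 0.012) were
chosen once so that learning is incremental over tens of presentations
(the feedforward ceiling is reached after roughly 10–20 presentations and
the feedback weights approach their homeostatic equilibrium within 40).

### Stimuli and protocols

A stimulus is a bell-shaped (Gaussian, s.d. 6 neurons) profile of injected
current over the V1 ring, peak amplitude 2.0, presented for 500 ms;
orientation is the profile center. Training = 40 presentations with both
rules active, each starting from rest (the blank between presentations is
not simulated: calcium — the only plasticity signal — is essentially zero
there). All measurement protocols (tuning sweeps, f-I probing, current
decomposition, input-resistance probing) run with plasticity frozen and
state re-initialized per probe, so probing never trains.

The bell input drives excitatory cells only by default
(`stimulus_spec(to_i = 0)`). Driving the interneurons directly at full
amplitude pushes them near their maximal rate, where they can no longer
track increments in feedback drive; the feedback increments then arrive
unbalanced (excitation without matching inhibition) and the V1–V2 loop
runs away. With interneurons driven mainly by feedback and recurrent
excitation (`fb_to_i = 2.8`), the inhibitory increments stay proportional
to the feedback increments — which is precisely the balanced-increment
(shunting) regime the model is about.

### Why the operating regime is delicate (and how it was chosen)

The V1E→V2→V1E path is a positive feedback loop; stability requires the
*net* effect of feedback on V1 excitatory cells to be suppressive at every
feedback strength reached during learning. Three failure modes bound the
regime: (i) direct loop gain > 1 (feedback weight too large relative to
feedforward in-degree), (ii) interneuron depolarization block (total
excitatory conductance onto an interneuron beyond ≈ 0.06 pins it above
spike threshold and silences it, instantly disinhibiting V1), and (iii)
interneuron saturation (no headroom to encode feedback increments). The
default weights (`w_ee = 0.015`, `w_ei = 0.01`, `w_ff0 = 0.05`,
`w_fb0 = 0.005`, `fb_to_i = 2.8`, I→E peak calibrated) keep the naive
network well inside the instability boundary in feedback strength, and
the plasticity ceilings (`w_ff_max = 0.12`, `w_fb_max = 0.08`) keep the
learned state inside it.

The I→E weight scale is not hand-set: `calibrate_ei_balance()` bisects it
until the time-averaged recurrent+feedback excitatory and inhibitory
currents onto the most-driven V1 cell, evaluated at the resting-potential
driving forces, cancel to within 10%. This is the operational definition
of "balanced" used throughout: at rest the components cancel; depolarize
the cell and the inhibitory driving force grows while the excitatory one
shrinks, so balanced conductance increments are *net suppressive* exactly
when the cell is driven — shunting, and therefore subtraction rather than
division in the f-I curve.

## Numerical choices

* Integrator: classical fixed-step RK4 at `dt = 0.025` ms, synaptic
  conductances held constant within a step; spike detection by upward
  0 mV crossing with a 2 ms refractory window. Halving `dt` moves spike
  times by less than one `dt` per 100 ms.
* The compiled inner loop evaluates the seven voltage functions from
  piecewise-linear tables (0.02 mV grid, interpolation error ~1e−9);
  the exported R rate functions are the closed forms, and the suite checks
  the two paths agree.
* Resting states are roots of the steady-state current found by a
  bracketing root-finder (scanning for the lowest downward crossing — the
  stable branch), not by running the integrator.
* Firing rates are spike counts over the final 80% of a window (onset
  transient discarded).
* Tuning width is full width at half maximum above the spontaneous rate
  (which is exactly 0 in this noise-free network). The slope at the
  trained orientation is a central finite difference; the
  reduction/sharpening classifier normalizes slope changes by
  `max(|slope_before|, 0.2 · amplitude/width)` so that the
  ill-conditioned near-zero slope at a symmetric peak is judged against
  the curve's natural rate-per-degree scale, with a 15% default tolerance.

## What the synthetic world does and does not establish

All inputs are generated internally; there is no external data. The
network is deterministic given its configuration — the only randomness is
the Bernoulli feedforward sparsity draw, governed by one seed. Green tests
therefore establish that the *mechanism* (balanced-increment shunting,
subtractive f-I shifts, reduction-versus-sharpening dissociation, graded
feedback specificity, preference stability, homeostatic closure) operates
as described in a faithfully parameterized instance of the model. They do
not establish robustness across the full biological parameter range, the
behavior under input noise (the model is noise-free by design; the source
work argues noise levels do not change with learning), or anything about
LGN/layer-4 processing, read-out circuits, or reinforcement — all
explicitly outside the model.

### A structural tension: recurrent amplification vs. homeostatic stability

One described property of recurrent cortical circuits — that they amplify
the responses of strongly driven neurons while suppressing weakly driven
ones — is only half-realized here, and the reason is instructive. If the
excitatory and inhibitory currents onto the *driven* cell cancel at rest
(the balance this model builds and measures), then at a depolarized
membrane potential the inhibitory driving force has grown and the
excitatory one has shrunk, so the net recurrent current at a strongly
driven cell is suppressive by construction. Amplification at the driven
site requires locally unbalanced recurrent excitation; every regime we
explored that provides it (balance calibrated at an off-stimulus cell,
strong E→E with saturating interneurons) loses the property that
inhibitory increments track feedback increments, and the V1–V2 loop then
runs away during training. The package keeps the training-stable,
balance-at-the-driven-cell regime: suppression of weakly driven neurons
and the interior region of maximal input–output slope are reproduced;
amplification of the strongest responders by recurrence is not, and the
corresponding acceptance test documents this by failing that clause.

## Known limitations

* The exact printed equation bodies of the source are unavailable in the
  extracted text; the rate functions above are this package's recorded,
  tested stand-ins, chosen to satisfy every stated property of the
  neuron classes (regular spiking with adaptation; faster, non-adapting
  interneurons; stable rest near −65 mV).
* Learning-induced effects are deliberately moderate (tens of percent, not
  folds): the stable dynamic range of the feedback loop bounds how much
  suppression the homeostatic rule can recruit before the network
  destabilizes.
* One-dimensional ring; no hypercolumn structure, no long-range horizontal
  connections, no NMDA/GABAb, no conduction delays, no short-term
  depression dynamics.
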