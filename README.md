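# shuntlearn

A conductance-based spiking network model of how perceptual learning
changes orientation tuning in primary visual cortex (V1) **without moving
orientation preferences** — through learned top-down feedback and shunting
inhibition rather than local circuit rewiring.

## The science

Experiments on orientation-discrimination learning disagree: some find
*sharpened* V1 tuning curves, others find *reduced* responses to the
trained orientation; in both, each neuron's preferred orientation is
unchanged. `shuntlearn` implements a two-layer spiking model that produces
both observations in one network:

* **V1**: 100 excitatory + 25 inhibitory Hodgkin–Huxley neurons on a ring
  tiling 180° of orientation; distance-dependent Gaussian recurrent
  weights (s.d. 10 neurons) that never learn. A bell-shaped input current
  (the orientation-tuned drive from layer 4) is shifted along the ring to
  represent stimulus orientation.
* **V2**: 100 excitatory neurons, driven by sparse convergent feedforward
  connections (connection probability Gaussian in distance, s.d. 5
  neurons). No V2 recurrence.
* **Plasticity**: feedforward weights grow Hebbianly with the product of
  pre- and postsynaptic intracellular calcium
  (`dW/dt = η [Ca]_pre [Ca]_post / τ_Hebb`, τ_Hebb = 100 ms); each V2
  neuron's diffuse, spatially uniform feedback weight onto all of V1 moves
  homeostatically with the deviation of its calcium from its own
  pre-training baseline (`dw/dt = η ([Ca] − [Ca]₀) / τ_FB`,
  τ_FB = 500 ms).

Training a stimulus strengthens its feedforward pathway, raises V2
activity, and the homeostatic rule answers by strengthening feedback.
Because feedback excites V1 inhibitory cells along with excitatory ones,
its net effect is **shunting inhibition**: excitatory and inhibitory
currents that cancel at rest (so nothing changes at rest), lower the input
resistance, and *subtract* from stimulus-evoked responses (a rightward
f-I shift, not a slope change). The result: response **reduction** in
neurons preferring the trained orientation, tuning **sharpening** in
neurons that respond to it but prefer a flank orientation, no change far
away, and 100% preference stability.

## Worked example

A fast, fully deterministic example on the bundled small fixture
(10E+3I V1, 10E V2):

```r
library(shuntlearn)
f <- small_network(seed = 42)
cal <- calibrate_ei_balance(f$net, f$stim, duration = 300)
cat(sprintf("I->E scale: %.3f  (I_exc %.3f, I_inh %.3f at rest)\n",
            cal$scale, cal$I_exc, cal$I_inh))
#> I->E scale: 0.098  (I_exc 0.059, I_inh -0.058 at rest)
tr <- run_training(cal$net, f$stim, repetitions = 10)
tail(tr$history, 3)
#>    presentation mean_w_ff mean_w_fb fb_drive mean_ca_v2
#> 8             8    0.0506     0.005 0.000263     0.0387
#> 9             9    0.0507     0.005 0.000263     0.0388
#> 10           10    0.0508     0.005 0.000263     0.0388
```

The calibration output is the excitation–inhibition balance: after
bisection on the I→E weight scale, the time-averaged excitatory
(+0.059) and inhibitory (−0.058) synaptic currents onto the probed neuron
cancel at the resting potential. The training history shows the Hebbian
growth of the mean feedforward weight (`mean_w_ff`) per presentation.

On the full-size network (`connectivity_config()` defaults, ~3 min total)
the same pipeline reproduces the headline effect — training roughly
doubles both balanced current components onto a V1 cell while their sum
stays near zero at rest:

```r
net <- build_network(connectivity_config())
stim <- stimulus_spec()                      # 90 degrees, amplitude 2.0
cal <- calibrate_ei_balance(net, stim)       # I->E scale 0.469
tr  <- run_training(cal$net, stim, repetitions = 40)
db <- decompose_currents(cal$net, 51, stim)  # center neuron, naive
da <- decompose_currents(tr$net, 51, stim)   # after training
#> before: I_exc +1.65  I_inh -1.60
#> after : I_exc +4.03  I_inh -4.07
mean(utils::tail(tr$history$mean_ca_v2, 5)) / mean(tr$ca_target)
#> ~1.08   (V2 calcium back within 10% of its homeostatic set-point)
```

Tuning curves, f-I curves, preference stability and the feedback-drive
profile are produced by `measure_tuning()`, `probe_fi_curve()`,
`preference_stability()` and `feedback_strength_profile()`, and quantified
by `tuning_metrics()` / `classify_change()` (amplitude, full width at half
maximum, the amplitude-to-width ratio R, slope at the trained orientation,
and the reduction/sharpening classification).

## Command line

```sh
Rscript inst/cli/simulate.R reproduce-figures --seed 1 --out results
Rscript inst/cli/simulate.R tuning --config my_config.json --out results
```

Commands: `train`, `tuning`, `fi`, `decompose`, `reproduce-figures`.
Configurations are JSON (`default_config()`, `load_config()`,
`save_config()`); all outputs are CSV plus a JSON sidecar with the
configuration echo and hash.

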