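Package: shuntlearn
Title: Spiking V1-V2 Network Model of Perceptual Learning via Feedback
    Shunting Inhibition
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) spiking network model of
    primary visual cortex (V1) coupled to a higher area (V2), with
    calcium-dependent Hebbian plasticity of feedforward connections and
    homeostatic plasticity of diffuse feedback connections.  Provides
    network construction with ring topology and distance-dependent
    connectivity, excitation-inhibition balance calibration, training and
    measurement protocols (orientation tuning curves, f-I curves,
    synaptic-current decomposition), and tuning-curve analysis (amplitude,
    width, amplitude-to-width ratio, slope, reduction-versus-sharpening
    classification).  Reproduces shunting-inhibition phenomena: balanced
    excitatory/inhibitory currents whose amplitudes grow with training, a
    subtractive (rightward) f-I shift, response reduction and tuning
    sharpening without loss of orientation preference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
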