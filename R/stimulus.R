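#' Oriented stimulus specification
#'
#' A bell-shaped (Gaussian) profile of injected current over the V1
#' orientation axis, standing in for the orientation-tuned drive from layer
#' 4.  Different orientations are modeled by shifting the profile's center
#' along the one-dimensional network.
#'
#' @param center center orientation (degrees, in `[0, 180)` on the circular
#'   topology).
#' @param amplitude peak injected current (per-unit-area current units).
#' @param width Gaussian s.d. of the profile, in neuron units.
#' @param duration presentation duration (ms).
#' @param to_i scale of the drive delivered to inhibitory V1 cells relative
#'   to excitatory cells.  Default 0: the interneurons are driven by
#'   feedback and recurrent excitation, not by the bell directly — direct
#'   drive saturates them and removes the headroom the balanced-increment
#'   (shunting) mechanism needs.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(center = 90, amplitude = 2, width = 6,
                          duration = 500, to_i = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (width <= 0) stop("width must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(center = center, amplitude = amplitude, width = width,
                 duration = duration, to_i = to_i),
            class = "stimulus_spec")
}

#' Per-neuron input currents for an oriented stimulus
#'
#' Evaluates the bell profile at every V1 neuron's position (excitatory and
#' inhibitory) and returns the external-current list consumed by
#' [advance()].  V2 receives no direct stimulus: it is driven only through
#' the feedforward pathway.
#'
#' @param spec a [stimulus_spec()].
#' @param net a [build_network()] result.
#' @return list with numeric vectors `e1`, `i1`, `e2`.
#' @export
stimulus_input <- function(spec, net) {
  n <- net$n_v1_e
  cpos <- orientation_to_pos(spec$center, n)
  if (net$config$topology == "circular") {
    cpos <- cpos %% n
  } else if (cpos < 0 || cpos > n - 1) {
    stop("stimulus center outside the bounded orientation domain")
  }
  pos <- neuron_positions(n, net$n_v1_i, net$n_v2_e)
  d_e <- ring_distance(pos$e1, cpos, n, net$config$topology)
  d_i <- ring_distance(pos$i1, cpos, n, net$config$topology)
  list(e1 = spec$amplitude * gauss_of_distance(d_e, spec$width),
       i1 = spec$to_i * spec$amplitude * gauss_of_distance(d_i, spec$width),
       e2 = rep(0, net$n_v2_e))
}

#' @rdname stimulus_input
#' @export
make_oriented_input <- stimulus_input
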