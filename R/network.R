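#' Connectivity configuration
#'
#' All sizes, peak weights, connectivity widths and seeds needed to build the
#' two-layer architecture.  Defaults are the full-size network: 100
#' excitatory + 25 inhibitory V1 neurons and 100 excitatory V2 neurons, with
#' distance-dependent recurrent weights (Gaussian of ring distance,
#' s.d. = 10 neurons), probabilistic convergent feedforward connectivity
#' (Gaussian connection probability, s.d. = 5 neurons) and uniform feedback
#' fan-out.
#'
#' Peak synaptic weights are per-connection maximal conductances; they were
#' chosen (and `w_ie` subsequently calibrated, see [calibrate_ei_balance()])
#' to give regular spiking at tens of Hz under the default bell stimulus
#' with balanced recurrent excitation and inhibition.
#'
#' @param n_v1_e,n_v1_i,n_v2_e population sizes.
#' @param w_ee,w_ei,w_ie,w_ii peak recurrent weights (E->E, E->I, I->E,
#'   I->I).  `w_ii = 0` by default: no I->I coupling.
#' @param recurrent_sd Gaussian s.d. of recurrent weight profiles (neurons).
#' @param ff_sd Gaussian s.d. of feedforward connection probability
#'   (neurons).
#' @param ff_p_peak feedforward connection probability at distance 0.
#' @param w_ff0 initial magnitude of existing feedforward connections.
#' @param w_fb0 initial (naive) feedback weight per V2 neuron.
#' @param fb_to_i scale of feedback conductance onto V1 inhibitory cells
#'   relative to excitatory cells.
#' @param topology `"circular"` (ring; default, orientation is periodic) or
#'   `"bounded"` (line).
#' @param seed integer seed for the feedforward sparsity draw.
#' @return An object of class `connectivity_config`.
#' @export
connectivity_config <- function(n_v1_e = 100, n_v1_i = 25, n_v2_e = 100,
                                w_ee = 0.015, w_ei = 0.01, w_ie = 0.4,
                                w_ii = 0, recurrent_sd = 10, ff_sd = 5,
                                ff_p_peak = 0.5, w_ff0 = 0.05,
                                w_fb0 = 0.005, fb_to_i = 2.8,
                                topology = c("circular", "bounded"),
                                seed = 1L) {
  topology <- match.arg(topology)
  if (recurrent_sd <= 0 || ff_sd <= 0)
    stop("connectivity s.d. values must be > 0")
  if (any(c(w_ee, w_ei, w_ie, w_ii, w_ff0, w_fb0) < 0))
    stop("weights must be >= 0")
  if (ff_p_peak < 0 || ff_p_peak > 1)
    stop("ff_p_peak must be a probability")
  structure(as.list(environment()), class = "connectivity_config")
}

#' Distance on the orientation ring
#'
#' Distance between positions on the one-dimensional network, in units of V1
#' excitatory neurons.  Under the circular topology (orientation is
#' periodic) the distance is the shorter arc.
#'
#' @param a,b positions (neuron-index units, may be fractional).
#' @param n ring circumference (number of V1 excitatory positions).
#' @param topology `"circular"` or `"bounded"`.
#' @export
ring_distance <- function(a, b, n, topology = "circular") {
  d <- abs(a - b)
  if (topology == "circular") d <- pmin(d, n - d)
  d
}

gauss_of_distance <- function(d, sd) exp(-d^2 / (2 * sd^2))

#' Neuron positions along the orientation axis
#'
#' V1 excitatory neurons sit at integer positions `0 .. n_e - 1`, tiling
#' 180 degrees of orientation evenly (1.8 degrees per neuron at the default
#' size).  Inhibitory neurons interleave the same axis uniformly (one per
#' `n_e / n_i` excitatory cells, offset to the interval midpoints), and V2
#' neurons tile the axis at their own density.
#'
#' @param net a network (list with sizes), or pass sizes directly.
#' @return list of numeric position vectors `e1`, `i1`, `e2`.
#' @keywords internal
neuron_positions <- function(n_e1, n_i1, n_e2) {
  list(e1 = seq_len(n_e1) - 1,
       i1 = (seq_len(n_i1) - 0.5) * n_e1 / n_i1,
       e2 = (seq_len(n_e2) - 1) * n_e1 / n_e2)
}

#' Orientation/index conversion
#'
#' The orientation axis spans 180 degrees over the V1 excitatory ring.
#'
#' @param deg orientation in degrees; `pos` position in neuron units.
#' @param n_e1 number of V1 excitatory neurons.
#' @export
orientation_to_pos <- function(deg, n_e1 = 100) deg * n_e1 / 180

#' @rdname orientation_to_pos
#' @param pos position in neuron-index units.
#' @export
pos_to_orientation <- function(pos, n_e1 = 100) pos * 180 / n_e1

#' Build the V1 recurrent weight matrices
#'
#' Deterministic Gaussian-of-distance weight profiles for the E->E, E->I and
#' I->E pathways (and I->I if configured), peak at distance 0, s.d.
#' `recurrent_sd` neurons.  Matrices are target x source.  E->E autapses are
#' excluded.  These weights are fixed: recurrent connections do not change
#' with learning.
#'
#' @param config a [connectivity_config()].
#' @return list of matrices `W_EE`, `W_EI`, `W_IE`, `W_II`.
#' @export
build_v1_recurrent <- function(config) {
  pos <- neuron_positions(config$n_v1_e, config$n_v1_i, config$n_v2_e)
  n <- config$n_v1_e
  prof <- function(ptgt, psrc, peak) {
    d <- outer(ptgt, psrc, ring_distance, n = n, topology = config$topology)
    peak * gauss_of_distance(d, config$recurrent_sd)
  }
  W_EE <- prof(pos$e1, pos$e1, config$w_ee)
  diag(W_EE) <- 0
  list(W_EE = W_EE,
       W_EI = prof(pos$i1, pos$e1, config$w_ei),
       W_IE = prof(pos$e1, pos$i1, config$w_ie),
       W_II = prof(pos$i1, pos$i1, config$w_ii))
}

#' Build the feedforward connectivity (V1 E -> V2 E)
#'
#' Connections exist with Bernoulli probability
#' `ff_p_peak * exp(-d^2 / (2 ff_sd^2))` of the distance between the
#' corresponding V1 and V2 positions (convergent, compact representation).
#' Existing connections start at the uniform magnitude `w_ff0`.  The
#' sparsity pattern is frozen after construction; only magnitudes learn.
#'
#' @param config a [connectivity_config()].
#' @return list with weight matrix `W_FF` (V2 x V1) and logical mask `M_FF`.
#' @export
build_feedforward <- function(config) {
  pos <- neuron_positions(config$n_v1_e, config$n_v1_i, config$n_v2_e)
  d <- outer(pos$e2, pos$e1, ring_distance, n = config$n_v1_e,
             topology = config$topology)
  p <- config$ff_p_peak * gauss_of_distance(d, config$ff_sd)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(config$seed)
  M <- matrix(stats::runif(length(p)) < p, nrow = nrow(p))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(W_FF = M * config$w_ff0, M_FF = M)
}

#' Build the feedback weights (V2 E -> all of V1)
#'
#' One scalar weight per V2 neuron, applied identically to every V1 neuron
#' (excitatory and inhibitory): the feedback is diffuse and untuned before
#' learning.
#'
#' @param config a [connectivity_config()].
#' @return numeric vector of length `n_v2_e`.
#' @export
build_feedback <- function(config) {
  rep(config$w_fb0, config$n_v2_e)
}

#' Assemble the two-layer network
#'
#' Builds all weight structures, attaches neuron/synapse/plasticity
#' parameters, and returns the simulation-ready architecture.  With a fixed
#' config (including its seed) the result is fully deterministic.
#'
#' @param config a [connectivity_config()].
#' @param params_e,params_i neuron parameter sets (defaults: the excitatory
#'   and inhibitory classes of [neuron_params()]).
#' @param syn a [synapse_params()].
#' @param plasticity a [plasticity_params()].
#' @param ca_inc calcium influx per spike (arbitrary units; sets the scale
#'   of the activity variable used by both plasticity rules and `I_AHP`).
#' @param refrac spike-detection refractory window (ms).
#' @return An object of class `shunt_network`.
#' @export
build_network <- function(config = connectivity_config(),
                          params_e = neuron_params("excitatory"),
                          params_i = neuron_params("inhibitory"),
                          syn = synapse_params(),
                          plasticity = plasticity_params(),
                          ca_inc = 0.2, refrac = 2) {
  rec <- build_v1_recurrent(config)
  ff <- build_feedforward(config)
  net <- c(list(n_v1_e = config$n_v1_e, n_v1_i = config$n_v1_i,
                n_v2_e = config$n_v2_e),
           rec, ff,
           list(w_fb = build_feedback(config),
                fb_to_i = config$fb_to_i,
                params_e = params_e, params_i = params_i, syn = syn,
                plasticity = plasticity, ca_inc = ca_inc, refrac = refrac,
                config = config))
  structure(net, class = "shunt_network")
}

#' @export
print.shunt_network <- function(x, ...) {
  cat("Two-layer conductance-based network\n")
  cat(sprintf("  V1: %d excitatory + %d inhibitory; V2: %d excitatory\n",
              x$n_v1_e, x$n_v1_i, x$n_v2_e))
  cat(sprintf("  feedforward connections: %d (of %d possible)\n",
              sum(x$M_FF), length(x$M_FF)))
  cat(sprintf("  topology: %s; seed: %d\n",
              x$config$topology, x$config$seed))
  cat(sprintf("  mean W_FF (existing): %.4g; mean w_FB: %.4g\n",
              mean(x$W_FF[x$M_FF]), mean(x$w_fb)))
  invisible(x)
}

#' Calibrate the excitation-inhibition balance
#'
#' Finds the scaling of the I->E weights such that, during a probe stimulus,
#' the time-averaged excitatory and inhibitory synaptic currents onto a V1
#' excitatory neuron *at rest* cancel:
#' `|g_e (V_ee - V_rest) + g_i (V_ie - V_rest)| <= tol * g_e (V_ee - V_rest)`
#' where the conductances are time averages over the probe window.  The
#' probed cell is, by default, the most-driven neuron (the stimulus
#' center).  Calibrating there makes the recurrent-plus-feedback input to
#' the responding population cancel at rest — the operating definition of
#' shunting used throughout — and, importantly, it sets the inhibition
#' strong enough that increments of feedback drive recruit at least
#' rest-balancing inhibitory increments, which is what keeps the V1-V2
#' feedback loop stable during learning.  Solved by bisection on the
#' scale; the residual is monotone decreasing in the scale.
#'
#' @param net a [build_network()] result (with the un-scaled `W_IE`).
#' @param stimulus a [stimulus_spec()] used as the probe drive.
#' @param tol balance tolerance as a fraction of the excitatory component.
#' @param bracket search interval for the scale.
#' @param duration probe duration (ms) over which currents are averaged.
#' @param max_iter bisection iterations.
#' @param probe index of the probed V1 excitatory neuron; default the cell
#'   at the stimulus center.
#' @return list with `scale` (the ratio applied to `W_IE`), `net` (the
#'   calibrated network), the `probe` used, and diagnostic time-averaged
#'   `I_exc`, `I_inh` (currents at rest driving force) and `residual`.
#' @export
calibrate_ei_balance <- function(net, stimulus, tol = 0.1,
                                 bracket = c(0, 40), duration = 300,
                                 max_iter = 40, probe = NULL) {
  rest <- resting_state(net$params_e, syn = net$syn)
  Vr <- rest$V
  if (is.null(probe)) {
    ctr <- orientation_to_pos(stimulus$center, net$n_v1_e) %% net$n_v1_e
    probe <- which.min(ring_distance(
      neuron_positions(net$n_v1_e, net$n_v1_i, net$n_v2_e)$e1, ctr,
      net$n_v1_e, net$config$topology))
  }
  measure <- function(scale) {
    m <- net
    m$W_IE <- net$W_IE * scale
    st <- init_state(m)
    out <- advance(m, st, input = stimulus_input(stimulus, m),
                   duration = duration, record = probe)
    g_e <- out$raw$mean_g_exc[1]
    g_i <- out$raw$mean_g_inh[1]
    c(I_exc = g_e * (m$syn$V_ee - Vr), I_inh = g_i * (m$syn$V_ie - Vr))
  }
  base <- measure(bracket[1])
  if (base[["I_exc"]] <= 1e-12) {
    net$W_IE <- net$W_IE * 0
    return(list(scale = 0, net = net, probe = probe, I_exc = 0, I_inh = 0,
                residual = 0))
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_hi <- sum(measure(hi))
  if (f_hi > 0)
    stop("calibration failed: even at scale ", hi,
         " inhibition does not balance excitation (residual ", f_hi, ")")
  res <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- measure(mid)
    resid <- sum(res)
    if (abs(resid) <= tol * res[["I_exc"]]) break
    if (resid > 0) lo <- mid else hi <- mid
  }
  if (abs(sum(res)) > tol * res[["I_exc"]])
    stop("calibration failed to converge; residual ", sum(res),
         " vs excitatory component ", res[["I_exc"]])
  net$W_IE <- net$W_IE * mid
  list(scale = mid, net = net, probe = probe, I_exc = res[["I_exc"]],
       I_inh = res[["I_inh"]], residual = sum(res))
}
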