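#' Initialize the network state at rest
#'
#' Every neuron starts at the resting point of its class (membrane potential
#' at the steady-state root, gating at voltage equilibrium), with zero
#' calcium and zero synaptic gating.
#'
#' @param net a [build_network()] result.
#' @return A state list consumed by [advance()].
#' @export
init_state <- function(net) {
  re <- resting_state(net$params_e, syn = net$syn)
  ri <- resting_state(net$params_i, syn = net$syn)
  rep_state <- function(r, n) {
    list(V = rep(r$V, n), m = rep(r$m, n), h = rep(r$h, n),
         n = rep(r$n, n), Ca = rep(0, n), last = rep(NA_real_, n))
  }
  e1 <- rep_state(re, net$n_v1_e)
  i1 <- rep_state(ri, net$n_v1_i)
  e2 <- rep_state(re, net$n_v2_e)
  list(V_e1 = e1$V, m_e1 = e1$m, h_e1 = e1$h, n_e1 = e1$n, Ca_e1 = e1$Ca,
       last_e1 = e1$last,
       V_i1 = i1$V, m_i1 = i1$m, h_i1 = i1$h, n_i1 = i1$n, Ca_i1 = i1$Ca,
       last_i1 = i1$last,
       V_e2 = e2$V, m_e2 = e2$m, h_e2 = e2$h, n_e2 = e2$n, Ca_e2 = e2$Ca,
       last_e2 = e2$last,
       s_e1 = rep(0, net$n_v1_e), s_i1 = rep(0, net$n_v1_i),
       s_e2 = rep(0, net$n_v2_e), t = 0)
}

#' Advance the network
#'
#' Integrates the coupled network for `duration` ms under piecewise-constant
#' external drive, optionally with the plasticity rules active, optionally
#' recording membrane potential and decomposed synaptic currents for chosen
#' V1 excitatory neurons.
#'
#' @param net a [build_network()] result.
#' @param state a state list from [init_state()] or a previous call.
#' @param input external current: a list with vectors `e1`, `i1`, `e2`
#'   (lengths matching the populations); missing entries are zero.  See
#'   [stimulus_input()].
#' @param duration simulated time (ms).
#' @param dt integration step (ms); default 0.025.
#' @param plastic_ff,plastic_fb apply the Hebbian feedforward / homeostatic
#'   feedback rule at every step.
#' @param ca_target homeostatic calcium set-point: one value per V2 neuron
#'   (each neuron's own baseline time-averaged calcium); a scalar is
#'   recycled.  Required if `plastic_fb`.
#' @param record integer indices of V1 excitatory neurons to record.
#' @param record_every record every this many steps (default 10, i.e. every
#'   0.25 ms at the default dt).
#' @return An object of class `sim_result`: list with `spikes` (data frame
#'   per population), `traces`, final `state`, updated `net` (weights
#'   changed only if plasticity was on), and summary scalars
#'   (`mean_fb_drive`, `mean_ca_v2`, per-neuron mean calcium and recorded
#'   mean conductances in `raw`).
#' @export
advance <- function(net, state, input = NULL, duration, dt = 0.025,
                    plastic_ff = FALSE, plastic_fb = FALSE,
                    ca_target = numeric(0),
                    record = integer(0), record_every = 10L) {
  if (plastic_fb) {
    if (any(!is.finite(ca_target)) || any(ca_target < 0))
      stop("plastic_fb requires non-negative, finite ca_target")
    ca_target <- rep_len(ca_target, net$n_v2_e)
  } else {
    ca_target <- rep(0, net$n_v2_e)
  }
  z <- function(n) rep(0, n)
  I_e1 <- if (!is.null(input$e1)) input$e1 else z(net$n_v1_e)
  I_i1 <- if (!is.null(input$i1)) input$i1 else z(net$n_v1_i)
  I_e2 <- if (!is.null(input$e2)) input$e2 else z(net$n_v2_e)
  out <- advance_cpp(net, state, I_e1, I_i1, I_e2, duration, dt,
                     plastic_ff, plastic_fb, ca_target,
                     as.integer(record), as.integer(record_every))
  net$W_FF <- out$W_FF
  net$w_fb <- out$w_fb
  structure(list(
    spikes = list(e1 = out$spikes_e1, i1 = out$spikes_i1, e2 = out$spikes_e2),
    traces = out$traces,
    state = out$state,
    net = net,
    mean_fb_drive = out$mean_fb_drive,
    mean_ca_v2 = out$mean_ca_v2,
    raw = out[c("mean_ca_v2_per_neuron", "mean_ca_v1_per_neuron",
                "mean_g_exc", "mean_g_inh")],
    duration = duration, dt = dt), class = "sim_result")
}

#' Firing rates from a spike data frame
#'
#' Mean firing rate (Hz) per neuron over a time window.  By default the
#' onset transient is discarded: the window covers the final
#' `keep_fraction` of `[t0, t1]`.
#'
#' @param spikes data frame with columns `time` (ms) and `neuron`.
#' @param n number of neurons in the population.
#' @param t0,t1 window limits (ms).
#' @param keep_fraction fraction of the window, anchored at its end, used
#'   for counting (default 0.8).
#' @return numeric vector of rates (Hz), one per neuron.
#' @export
firing_rates <- function(spikes, n, t0, t1, keep_fraction = 0.8) {
  lo <- t1 - keep_fraction * (t1 - t0)
  keep <- spikes$time > lo & spikes$time <= t1
  counts <- tabulate(spikes$neuron[keep], nbins = n)
  counts / ((t1 - lo) / 1000)
}
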