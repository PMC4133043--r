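#' Membrane derivatives
#'
#' Right-hand side of the single-compartment conductance-based membrane
#' equations: leak, transient sodium, delayed-rectifier potassium,
#' high-threshold calcium and (excitatory cells only) calcium-dependent
#' after-hyperpolarization currents, plus synaptic and injected current.
#' Synaptic currents use the `g * (E - V)` convention (positive
#' depolarizes).  Calcium decays with `tau_Ca`; its spike-triggered influx is
#' handled by the stepping functions, not here.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param g_exc,g_inh synaptic conductances onto the cell.
#' @param I_inj injected current.
#' @param syn a [synapse_params()] (reversal potentials).
#' @return Named list of time derivatives `dV`, `dm`, `dh`, `dn`, `dCa`.
#' @export
hh_derivatives <- function(state, params, g_exc = 0, g_inh = 0, I_inj = 0,
                           syn = synapse_params()) {
  V <- state$V
  r <- hh_rates(V)
  mca <- hh_mca_inf(V)
  I <- params$g_L * (params$V_L - V) +
    params$g_Na * state$m^3 * state$h * (params$V_Na - V) +
    params$g_K * state$n^4 * (params$V_K - V) +
    params$g_Ca * mca^2 * (params$V_Ca - V) +
    g_exc * (syn$V_ee - V) +
    g_inh * (syn$V_ie - V) +
    I_inj
  if (isTRUE(params$has_ahp))
    I <- I + params$g_AHP * state$Ca * (params$V_K - V)
  list(dV = I,
       dm = r$alpha_m * (1 - state$m) - r$beta_m * state$m,
       dh = r$alpha_h * (1 - state$h) - r$beta_h * state$h,
       dn = r$alpha_n * (1 - state$n) - r$beta_n * state$n,
       dCa = -state$Ca / params$tau_Ca)
}

#' Advance one neuron by one timestep
#'
#' Reference (pure R) single-step integrator: classical fourth-order
#' Runge-Kutta with synaptic conductances held constant over the step,
#' followed by spike detection (upward crossing of 0 mV with a 2 ms
#' refractory window) which triggers the calcium influx `ca_inc`.
#'
#' This is the readable specification of the dynamics; bulk simulation uses
#' the identical compiled kernel (see [simulate_neuron()] and [advance()]),
#' and the test suite checks the two agree.
#'
#' @inheritParams hh_derivatives
#' @param dt timestep (ms); must be within the stability range of the
#'   explicit integrator (<= 0.05 ms recommended).
#' @param t current time (ms), used for refractoriness bookkeeping.
#' @param ca_inc calcium influx per detected spike.
#' @param refrac refractory window for spike detection (ms).
#' @return Updated [neuron_state()] with attribute `spiked` (logical).
#' @export
step_neuron <- function(state, params, g_exc = 0, g_inh = 0, I_inj = 0,
                        dt = 0.025, t = 0, syn = synapse_params(),
                        ca_inc = 0.2, refrac = 2) {
  if (!all(is.finite(c(state$V, state$m, state$h, state$n, state$Ca,
                       g_exc, g_inh, I_inj))))
    stop("integration diverged: non-finite state or current at t = ", t)
  y <- state
  k1 <- hh_derivatives(y, params, g_exc, g_inh, I_inj, syn)
  mid1 <- rk_partial(y, k1, dt / 2)
  k2 <- hh_derivatives(mid1, params, g_exc, g_inh, I_inj, syn)
  mid2 <- rk_partial(y, k2, dt / 2)
  k3 <- hh_derivatives(mid2, params, g_exc, g_inh, I_inj, syn)
  end <- rk_partial(y, k3, dt)
  k4 <- hh_derivatives(end, params, g_exc, g_inh, I_inj, syn)
  wsum <- function(f) (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]]) / 6
  new <- list(V = y$V + dt * wsum("dV"),
              m = clamp01(y$m + dt * wsum("dm")),
              h = clamp01(y$h + dt * wsum("dh")),
              n = clamp01(y$n + dt * wsum("dn")),
              Ca = max(0, y$Ca + dt * wsum("dCa")),
              last_spike = y$last_spike)
  spiked <- FALSE
  if (y$V < 0 && new$V >= 0 &&
      (is.na(y$last_spike) || (t + dt) - y$last_spike >= refrac)) {
    spiked <- TRUE
    new$last_spike <- t + dt
    new$Ca <- new$Ca + ca_inc
  }
  structure(new, class = "neuron_state", spiked = spiked)
}

rk_partial <- function(y, k, hdt) {
  list(V = y$V + hdt * k$dV, m = y$m + hdt * k$dm, h = y$h + hdt * k$dh,
       n = y$n + hdt * k$dn, Ca = y$Ca + hdt * k$dCa,
       last_spike = y$last_spike)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Update synaptic gating variables
#'
#' Between presynaptic spikes each gating variable decays exponentially with
#' its receptor time constant (AMPA 2 ms for excitatory sources, GABAa 2 ms
#' for inhibitory sources); a presynaptic spike increments the source's
#' gating variable by 1.
#'
#' @param gating list with numeric vectors `s_e` (one per excitatory source)
#'   and `s_i` (one per inhibitory source).
#' @param spikes_e,spikes_i logical (or 0/1) spike indicators per source.
#' @param dt elapsed time (ms), > 0.
#' @param syn a [synapse_params()].
#' @return Updated gating list.
#' @export
update_synaptic_gating <- function(gating, spikes_e = NULL, spikes_i = NULL,
                                   dt, syn = synapse_params()) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(gating$s_e < 0) || any(gating$s_i < 0))
    stop("gating variables must be >= 0")
  s_e <- gating$s_e * exp(-dt / syn$tau_ampa)
  s_i <- gating$s_i * exp(-dt / syn$tau_gabaa)
  if (!is.null(spikes_e)) s_e <- s_e + as.numeric(spikes_e)
  if (!is.null(spikes_i)) s_i <- s_i + as.numeric(spikes_i)
  list(s_e = s_e, s_i = s_i)
}

#' Synaptic current onto one neuron, decomposed by sign
#'
#' Computes the excitatory (AMPA) and inhibitory (GABAa) synaptic currents
#' separately — the decomposition underlying the balanced-current analysis.
#' The total current applied to the membrane is their sum.
#'
#' @param target_class `"excitatory"` or `"inhibitory"` (selects the AMPA
#'   reversal `V_ee` vs `V_ei`; both are 0 mV by default).
#' @param V membrane potential of the target (mV).
#' @param gating list with `s_e`, `s_i` vectors (per source neuron).
#' @param weights list with `w_e`, `w_i` weight vectors conforming to the
#'   source populations (`w_i` may be length 0 for targets receiving no
#'   inhibition).
#' @param syn a [synapse_params()].
#' @return list with `excitatory`, `inhibitory` and `total` currents.
#' @export
synaptic_current <- function(target_class = c("excitatory", "inhibitory"),
                             V, gating, weights, syn = synapse_params()) {
  target_class <- match.arg(target_class)
  if (length(weights$w_e) != length(gating$s_e))
    stop("excitatory weight vector does not conform to source population")
  if (length(weights$w_i) != length(gating$s_i))
    stop("inhibitory weight vector does not conform to source population")
  E_exc <- if (target_class == "excitatory") syn$V_ee else syn$V_ei
  I_exc <- syn$f_e * sum(weights$w_e * gating$s_e) * (E_exc - V)
  I_inh <- if (length(weights$w_i))
    syn$f_i * sum(weights$w_i * gating$s_i) * (syn$V_ie - V) else 0
  list(excitatory = I_exc, inhibitory = I_inh, total = I_exc + I_inh)
}

#' Simulate a single isolated neuron
#'
#' Runs the compiled single-neuron integrator for `duration` ms under
#' constant synaptic conductances and injected current, starting from
#' `state` (default: the resting state).
#'
#' @inheritParams step_neuron
#' @param duration simulated time (ms).
#' @param state initial [neuron_state()]; default the resting state.
#' @param record_every record `V` and `Ca` every this many steps (0 = none).
#' @return list with `spikes` (times, ms), final `state`, and recorded
#'   `time`, `V`, `Ca` traces.
#' @export
simulate_neuron <- function(params, I_inj = 0, duration = 500, g_exc = 0,
                            g_inh = 0, dt = 0.025, state = NULL,
                            syn = synapse_params(), ca_inc = 0.2, refrac = 2,
                            record_every = 40) {
  if (is.null(state)) state <- resting_state(params, g_exc, g_inh, 0, syn)
  simulate_neuron_cpp(params, state, g_exc, g_inh, syn$V_ee, syn$V_ie,
                      I_inj, duration, dt, ca_inc, refrac, record_every)
}
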