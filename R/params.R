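#' Hodgkin-Huxley neuron parameters
#'
#' Parameter set for a single-compartment conductance-based neuron of the
#' regular-spiking pyramidal type (excitatory) or fast interneuron type
#' (inhibitory).  All conductances are per-unit-area maximal conductances in
#' the model's dimensionless convention (membrane capacitance is 1);
#' potentials are in mV and time constants in ms.
#'
#' The two classes share the spike-generating machinery.  They differ in two
#' ways: inhibitory cells lack the calcium-dependent after-hyperpolarization
#' current `I_AHP` (hence show no spike-frequency adaptation) and have twice
#' the leak conductance (`g_L` = 0.1 vs 0.05), which halves the membrane time
#' constant and makes their dynamics faster.
#'
#' @param class `"excitatory"` or `"inhibitory"`.
#' @param ... named overrides for any field (`g_L`, `g_Na`, `g_K`, `g_Ca`,
#'   `g_AHP`, `V_L`, `V_Na`, `V_K`, `V_Ca`, `tau_Ca`, `has_ahp`).
#' @return An object of class `neuron_params`: a named list of parameters.
#' @examples
#' pe <- neuron_params("excitatory")
#' pi <- neuron_params("inhibitory")
#' pi$g_L / pe$g_L  # 2: inhibitory membrane is twice as fast
#' @export
neuron_params <- function(class = c("excitatory", "inhibitory"), ...) {
  class <- match.arg(class)
  p <- list(
    g_L   = if (class == "excitatory") 0.05 else 0.1,
    g_Na  = 100,
    g_K   = 40,
    g_Ca  = 0.9,
    g_AHP = if (class == "excitatory") 0.05 else 0,
    V_L   = -65,
    V_Na  = 55,
    V_K   = -80,
    V_Ca  = 120,
    tau_Ca = 100,
    has_ahp = class == "excitatory"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$class <- class
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  g <- unlist(p[c("g_L", "g_Na", "g_K", "g_Ca", "g_AHP")])
  if (any(!is.finite(g)) || any(g < 0))
    stop("all conductances must be finite and >= 0")
  if (!(p$V_K < p$V_L && p$V_L < p$V_Na))
    stop("reversal potentials must satisfy V_K < V_L < V_Na")
  if (p$tau_Ca <= 0) stop("tau_Ca must be > 0")
  invisible(p)
}

#' Synapse parameters
#'
#' AMPA (excitatory) and GABAa (inhibitory) synapse constants.  Synaptic
#' currents follow the driving-force convention `I = g * s * (E - V)`, so the
#' GABAa reversal is -80 mV (equal to `V_K`): at rest (-65 mV) the inhibitory
#' driving force is hyperpolarizing while the AMPA driving force (reversal
#' 0 mV) is depolarizing, and balanced conductances cancel at rest — the
#' substrate of shunting inhibition.
#'
#' `f_e` and `f_i` are short-term depression factors; they default to 1 (no
#' depression), and no depression dynamics are modeled.
#'
#' @param ... named overrides (`tau_ampa`, `tau_gabaa`, `V_ee`, `V_ei`,
#'   `V_ie`, `f_e`, `f_i`).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(...) {
  p <- list(tau_ampa = 2, tau_gabaa = 2,
            V_ee = 0, V_ei = 0, V_ie = -80,
            f_e = 1, f_i = 1)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown synapse parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (p$tau_ampa <= 0 || p$tau_gabaa <= 0)
    stop("synaptic time constants must be > 0")
  if (p$V_ie > p$V_ee)
    stop("inhibitory reversal must not exceed excitatory reversal")
  if (p$f_e <= 0 || p$f_e > 1 || p$f_i <= 0 || p$f_i > 1)
    stop("depression factors must lie in (0, 1]")
  structure(p, class = "synapse_params")
}

#' Channel rate functions and steady-state gating
#'
#' Voltage-dependent opening/closing rates of the sodium (`m`, `h`) and
#' delayed-rectifier potassium (`n`) gates, in the regular-spiking
#' parameterization used throughout the model, plus the instantaneous
#' activation of the high-threshold calcium channel.
#'
#' @param V membrane potential (mV).
#' @return `hh_rates()`: named list of alpha/beta rates (1/ms).
#'   `hh_gating_inf()`: named vector of steady-state `m`, `h`, `n`.
#' @export
hh_rates <- function(V) {
  linexp <- function(x) ifelse(abs(x) < 1e-7, 1 + x / 2, x / (1 - exp(-x)))
  list(
    alpha_m = 1.28 * linexp((V + 48) / 4),
    beta_m  = 1.4 * linexp(-(V + 21) / 5),
    alpha_h = 0.128 * exp(-(V + 44) / 18),
    beta_h  = 4 / (1 + exp(-(V + 21) / 5)),
    alpha_n = 0.16 * linexp((V + 52) / 5),
    beta_n  = 0.5 * exp(-(V + 57) / 40)
  )
}

#' @rdname hh_rates
#' @export
hh_gating_inf <- function(V) {
  r <- hh_rates(V)
  c(m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' @rdname hh_rates
#' @export
hh_mca_inf <- function(V) 1 / (1 + exp(-(V + 20) / 9))

#' Resting state of a neuron
#'
#' Solves for the resting membrane potential (root of the steady-state
#' membrane current with gating variables at their voltage equilibria) with a
#' bracketing root-finder, and returns the full resting state.  The rest
#' point is close to, but not exactly, the leak reversal because the sodium,
#' potassium and calcium window currents are not zero at rest.
#'
#' @param params a [neuron_params()] object.
#' @param g_exc,g_inh tonic synaptic conductances (default 0).
#' @param I_inj tonic injected current (default 0).
#' @param syn a [synapse_params()] object (reversal potentials).
#' @param interval search bracket for the resting potential (mV).
#' @return A `neuron_state` list: `V`, `m`, `h`, `n`, `Ca`, `last_spike`.
#' @export
resting_state <- function(params, g_exc = 0, g_inh = 0, I_inj = 0,
                          syn = synapse_params(),
                          interval = c(-90, -40)) {
  f <- function(V) hh_steady_current_cpp(params, V, 0, g_exc, g_inh,
                                         syn$V_ee, syn$V_ie, I_inj)
  # Locate the lowest downward zero-crossing (the stable fixed point); the
  # steady-state current turns positive again on the spiking branch, so a
  # blind bracket over the whole interval can fail.
  grid <- seq(interval[1], interval[2], by = 0.5)
  fg <- vapply(grid, f, numeric(1))
  k <- which(fg[-length(fg)] > 0 & fg[-1] <= 0)
  if (!length(k))
    stop("no stable resting point in [", interval[1], ", ", interval[2],
         "] mV for this parameter set")
  root <- stats::uniroot(f, c(grid[k[1]], grid[k[1] + 1]), tol = 1e-10)$root
  g <- hh_gating_inf(root)
  neuron_state(V = root, m = g[["m"]], h = g[["h"]], n = g[["n"]], Ca = 0)
}

#' Neuron state container
#'
#' @param V membrane potential (mV); `m`, `h`, `n` gating variables in
#'   `[0, 1]`; `Ca` intracellular calcium (arbitrary units, >= 0);
#'   `last_spike` time of the most recent spike (ms) or `NA`.
#' @param m,h,n,Ca,last_spike see above.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V = -65, m = 0, h = 1, n = 0, Ca = 0,
                         last_spike = NA_real_) {
  if (any(c(m, h, n) < 0) || any(c(m, h, n) > 1))
    stop("gating variables must lie in [0, 1]")
  if (Ca < 0) stop("calcium must be >= 0")
  if (!is.finite(V) || V < -120 || V > 80)
    stop("membrane potential outside plausible range [-120, 80] mV")
  structure(list(V = V, m = m, h = h, n = n, Ca = Ca,
                 last_spike = as.numeric(last_spike)),
            class = "neuron_state")
}
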