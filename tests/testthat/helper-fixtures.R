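# Shared fixtures and independent oracles for the test suite.

# Small deterministic fixture: 12E + 3I V1 (integer interleaving, so ring
# shifts by 4 are exact symmetries), 12E V2.
fix_net <- function(seed = 42L, ...) {
  small_network(seed = seed, n_v1_e = 12, n_v1_i = 3, n_v2_e = 12, ...)
}

# Analytic response of a passive membrane (all voltage-gated conductances
# zero) to a current step from rest: V(t) = V_L + (I/g_L) (1 - e^(-g_L t)).
passive_response <- function(t, I, g_L, V_L = -65) {
  V_L + (I / g_L) * (1 - exp(-g_L * t))
}

# Closed-form weight increment of the Hebbian rule under constant pre/post
# calcium c over time T.
hebb_closed_form <- function(c_pre, c_post, T, eta, tau) {
  eta * c_pre * c_post * T / tau
}

expect_spikes_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(a$time, b$time, tolerance = tol)
    expect_equal(a$neuron, b$neuron)
  }
}

# Gaussian synthetic tuning curve on a probe grid (for analysis tests).
gauss_curve <- function(probes, center = 90, amp = 30, sd_deg = 12,
                        neuron_id = 1, condition = "x") {
  d <- ((probes - center + 90) %% 180) - 90
  structure(list(orientation = probes, rate = amp * exp(-d^2 / (2 * sd_deg^2)),
                 neuron_id = neuron_id, condition = condition),
            class = "tuning_curve")
}
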