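test_that("parameter containers enforce their invariants", {
  pe <- neuron_params("excitatory")
  pi_ <- neuron_params("inhibitory")
  expect_true(pe$has_ahp)
  expect_false(pi_$has_ahp)
  expect_identical(pi_$g_AHP, 0)
  expect_equal(pi_$g_L / pe$g_L, 2)  # inhibitory membrane twice as fast
  expect_error(neuron_params("excitatory", g_Na = -1), "conductance")
  expect_error(neuron_params("excitatory", V_K = -60), "V_K < V_L < V_Na")
  expect_error(neuron_params("excitatory", bogus = 1), "unknown")
  expect_error(synapse_params(tau_ampa = 0), "> 0")
  expect_error(synapse_params(V_ie = 80), "reversal")
  expect_error(neuron_state(m = 1.5), "gating")
  expect_error(neuron_state(Ca = -1), "calcium")
})

test_that("a neuron at rest stays within 5 mV of -65 mV for 500 ms", {
  # Oracle: the resting point is the root of the steady-state current,
  # found independently of the integrator by a bracketing root-finder.
  for (cls in c("excitatory", "inhibitory")) {
    p <- neuron_params(cls)
    rs <- resting_state(p)
    expect_lt(abs(rs$V - (-65)), 5)
    sim <- simulate_neuron(p, I_inj = 0, duration = 500)
    expect_equal(length(sim$spikes), 0)
    expect_lt(max(abs(sim$V - (-65))), 5)
    # and it truly sits at the fixed point: no drift from the root
    expect_lt(max(abs(sim$V - rs$V)), 0.01)
  }
})

test_that("excitatory cells adapt, inhibitory cells do not", {
  se <- simulate_neuron(neuron_params("excitatory"), I_inj = 3,
                        duration = 1000)
  si <- simulate_neuron(neuron_params("inhibitory"), I_inj = 3,
                        duration = 1000)
  isi_e <- diff(se$spikes)
  isi_i <- diff(si$spikes)
  expect_gt(length(isi_e), 5)
  expect_gt(length(isi_i), 5)
  # excitatory: intervals lengthen monotonically over the first 5 spikes
  expect_true(all(diff(isi_e[1:5]) > 0))
  # inhibitory: intervals settle to a constant within 5% after 5 spikes
  later <- isi_i[5:length(isi_i)]
  expect_lt(diff(range(later)) / mean(later), 0.05)
  # inhibitory membrane is faster: same current, more spikes
  expect_gt(length(si$spikes), length(se$spikes))
})

test_that("passive-limit membrane matches the analytic exponential to 1%", {
  p <- neuron_params("excitatory", g_Na = 0, g_K = 0, g_Ca = 0, g_AHP = 0)
  I <- 0.3
  sim <- simulate_neuron(p, I_inj = I, duration = 200, dt = 0.01,
                         state = neuron_state(V = -65, m = 0, h = 1, n = 0),
                         record_every = 100)
  expected <- passive_response(sim$time, I, p$g_L)
  # compare the deflection from rest, not the absolute potential
  err <- max(abs(sim$V - expected)) / (I / p$g_L)
  expect_lt(err, 0.01)
})

test_that("synaptic gating decays exponentially and increments on spikes", {
  g0 <- list(s_e = 1, s_i = 0)
  g2 <- update_synaptic_gating(g0, dt = 2)
  expect_equal(g2$s_e, exp(-1), tolerance = 1e-12)  # tau_AMPA = 2 ms
  expect_identical(g2$s_i, 0)                        # zero fixed point
  # monotone decay: longer silence, smaller gating
  spike <- update_synaptic_gating(list(s_e = 0, s_i = 0),
                                  spikes_e = 1, spikes_i = 1, dt = 0.025)
  g_short <- update_synaptic_gating(spike, dt = 2)
  g_long <- update_synaptic_gating(spike, dt = 10)
  expect_lt(g_long$s_e, g_short$s_e)
  expect_lt(g_long$s_i, g_short$s_i)
  expect_error(update_synaptic_gating(list(s_e = -1, s_i = 0), dt = 1),
               ">= 0")
  expect_error(update_synaptic_gating(g0, dt = 0), "> 0")
})

test_that("synaptic currents decompose by sign and vanish at reversal", {
  syn <- synapse_params()
  gat <- list(s_e = c(0.5, 0.2), s_i = 0.3)
  w <- list(w_e = c(0.1, 0.2), w_i = 0.4)
  # zero gating -> zero currents
  z <- synaptic_current("excitatory", -65, list(s_e = c(0, 0), s_i = 0), w)
  expect_identical(z$excitatory, 0)
  expect_identical(z$inhibitory, 0)
  # zero driving force at each reversal
  expect_equal(synaptic_current("excitatory", 0, gat, w)$excitatory, 0)
  expect_equal(synaptic_current("excitatory", syn$V_ie, gat, w)$inhibitory, 0)
  # decomposition consistency at an arbitrary potential
  cur <- synaptic_current("excitatory", -55, gat, w)
  expect_identical(cur$total, cur$excitatory + cur$inhibitory)
  expect_gt(cur$excitatory, 0)
  expect_lt(cur$inhibitory, 0)
  expect_error(synaptic_current("excitatory", -65, gat,
                                list(w_e = 0.1, w_i = 0.4)), "conform")
})

test_that("reference R stepper agrees with the compiled integrator", {
  p <- neuron_params("excitatory")
  st_r <- resting_state(p)
  sim <- simulate_neuron(p, I_inj = 2, duration = 5, g_exc = 0.02,
                         g_inh = 0.05, dt = 0.025, state = st_r,
                         record_every = 1)
  st <- st_r
  for (k in seq_len(200)) {
    st <- step_neuron(st, p, g_exc = 0.02, g_inh = 0.05, I_inj = 2,
                      dt = 0.025, t = (k - 1) * 0.025)
  }
  # compiled path uses rate lookup tables; agreement to ~1e-5 mV expected
  expect_equal(st$V, sim$state$V, tolerance = 1e-4)
  expect_equal(st$m, sim$state$m, tolerance = 1e-5)
  expect_equal(st$Ca, sim$state$Ca, tolerance = 1e-6)
})

test_that("gating variables stay in [0,1] under erratic drive", {
  p <- neuron_params("excitatory")
  st <- resting_state(p)
  set.seed(7)
  drives <- runif(300, -5, 15)
  for (k in seq_along(drives)) {
    st <- step_neuron(st, p, I_inj = drives[k], dt = 0.025,
                      t = (k - 1) * 0.025)
    expect_true(all(c(st$m, st$h, st$n) >= 0 & c(st$m, st$h, st$n) <= 1))
    expect_gte(st$Ca, 0)
  }
})

test_that("halving dt moves spike times by less than one dt per 100 ms", {
  p <- neuron_params("excitatory")
  s1 <- simulate_neuron(p, I_inj = 2, duration = 200, dt = 0.025)
  s2 <- simulate_neuron(p, I_inj = 2, duration = 200, dt = 0.0125)
  expect_equal(length(s1$spikes), length(s2$spikes))
  # budget: one dt per 100 ms of simulation
  expect_lt(max(abs(s1$spikes - s2$spikes)), 0.025 * 2)
})

test_that("non-finite input raises an integration error naming the time", {
  p <- neuron_params("excitatory")
  expect_error(step_neuron(resting_state(p), p, I_inj = NaN, t = 3.25),
               "diverged.*3.25")
  bad <- list(V = NaN, m = 0, h = 1, n = 0, Ca = 0, last_spike = NA_real_)
  expect_error(simulate_neuron(p, I_inj = 0, duration = 5, state = bad),
               "diverged")
})
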