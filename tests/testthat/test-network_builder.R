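test_that("connectivity config validates its fields", {
  expect_error(connectivity_config(recurrent_sd = 0), "s.d.")
  expect_error(connectivity_config(ff_sd = -1), "s.d.")
  expect_error(connectivity_config(w_ee = -0.1), ">= 0")
  expect_error(connectivity_config(ff_p_peak = 1.5), "probability")
})

test_that("ring distance obeys the circular metric", {
  expect_equal(ring_distance(0, 99, 100), 1)
  expect_equal(ring_distance(0, 50, 100), 50)
  expect_equal(ring_distance(0, 99, 100, topology = "bounded"), 99)
  expect_equal(ring_distance(3.5, 3.5, 100), 0)
})

test_that("recurrent weights are Gaussian in distance with the right peak", {
  cfg <- connectivity_config()
  w <- build_v1_recurrent(cfg)
  # E->E at distance d: peak * exp(-d^2 / (2 * 10^2)); autapses excluded
  expect_equal(w$W_EE[1, 11], cfg$w_ee * exp(-0.5))   # distance 10 = 1 s.d.
  expect_equal(w$W_EE[1, 2], cfg$w_ee * exp(-1 / 200))
  expect_equal(diag(w$W_EE), rep(0, 100))
  expect_equal(w$W_EE[1, 100], w$W_EE[1, 2])          # ring symmetry
  # E->I peak at distance 0 is exactly the pathway peak: inhibitory neuron
  # positions fall mid-interval, so probe the profile through a position hit
  d <- ring_distance(neuron_positions(100, 25, 100)$i1[1], 0:99, 100)
  expect_equal(w$W_EI[1, which.min(d)], cfg$w_ei * exp(-min(d)^2 / 200))
  # distance symmetry: weight depends only on |i - j|
  expect_equal(w$W_EE[10, 20], w$W_EE[20, 10])
  expect_equal(w$W_EE[10, 20], w$W_EE[50, 60])
})

test_that("feedforward sparsity is Bernoulli-Gaussian and seed-stable", {
  cfg <- connectivity_config()
  a <- build_feedforward(cfg)
  b <- build_feedforward(cfg)
  expect_identical(a$M_FF, b$M_FF)  # same seed, same pattern
  cfg2 <- connectivity_config(seed = 2L)
  expect_false(identical(a$M_FF, build_feedforward(cfg2)$M_FF))
  # existing connections carry the uniform initial magnitude
  expect_true(all(a$W_FF[a$M_FF] == cfg$w_ff0))
  expect_true(all(a$W_FF[!a$M_FF] == 0))
  # empirical connection frequency at distance 5 over many seeded draws:
  # expected p = peak * exp(-1/2), binomial check within 3 standard errors
  pos <- neuron_positions(100, 25, 100)
  d <- outer(pos$e2, pos$e1, ring_distance, n = 100)
  at5 <- d == 5
  draws <- unlist(lapply(1:50, function(s) {
    m <- build_feedforward(connectivity_config(seed = s))$M_FF
    m[at5]
  }))
  p_hat <- mean(draws)
  p_exp <- cfg$ff_p_peak * exp(-0.5)
  se <- sqrt(p_exp * (1 - p_exp) / length(draws))
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # probability at distance 0 equals the configured peak (same check)
  at0 <- d == 0
  draws0 <- unlist(lapply(1:50, function(s) {
    build_feedforward(connectivity_config(seed = s))$M_FF[at0]
  }))
  se0 <- sqrt(cfg$ff_p_peak * (1 - cfg$ff_p_peak) / length(draws0))
  expect_lt(abs(mean(draws0) - cfg$ff_p_peak), 3 * se0)
})

test_that("feedback fan-out is uniform and ablatable", {
  f <- fix_net()
  net <- f$net
  expect_equal(net$w_fb, rep(net$config$w_fb0, net$n_v2_e))
  # with w_fb = 0, V1 is independent of V2: zeroing the feedforward matrix
  # must not change V1 spiking
  n0 <- net; n0$w_fb <- rep(0, net$n_v2_e)
  n1 <- n0; n1$W_FF <- n1$W_FF * 0
  inp <- stimulus_input(f$stim, net)
  o0 <- advance(n0, init_state(n0), inp, duration = 150)
  o1 <- advance(n1, init_state(n1), inp, duration = 150)
  expect_spikes_equal(o0$spikes$e1, o1$spikes$e1)
  expect_spikes_equal(o0$spikes$i1, o1$spikes$i1)
  # but V2 did respond through the feedforward pathway
  expect_gt(nrow(o0$spikes$e2), 0)
})

test_that("architecture is deterministic given config and seed", {
  a <- fix_net()$net
  b <- fix_net()$net
  expect_identical(a[c("W_EE", "W_EI", "W_IE", "W_FF", "M_FF", "w_fb")],
                   b[c("W_EE", "W_EI", "W_IE", "W_FF", "M_FF", "w_fb")])
  inp <- stimulus_input(fix_net()$stim, a)
  oa <- advance(a, init_state(a), inp, duration = 150)
  ob <- advance(b, init_state(b), inp, duration = 150)
  expect_spikes_equal(oa$spikes$e1, ob$spikes$e1)
  expect_spikes_equal(oa$spikes$e2, ob$spikes$e2)
})

test_that("translation symmetry holds on the ring without feedforward noise", {
  # 12E/3I: one inhibitory cell per 4 excitatory cells, so a 4-neuron shift
  # is an exact symmetry of the deterministic part of the architecture.
  f <- fix_net(w_ff0 = 0)
  net <- f$net
  stim1 <- f$stim
  stim2 <- f$stim
  stim2$center <- stim1$center + 4 * 180 / net$n_v1_e
  r1 <- population_response(net, stim1)
  r2 <- population_response(net, stim2)
  shifted <- r1[((seq_len(net$n_v1_e) - 1 - 4) %% net$n_v1_e) + 1]
  expect_equal(r2, shifted)
})

test_that("degenerate calibration returns a zero ratio", {
  f <- fix_net(w_ee = 0, w_ff0 = 0, w_fb0 = 0)
  cal <- calibrate_ei_balance(f$net, f$stim, duration = 100)
  expect_identical(cal$scale, 0)
  expect_true(all(cal$net$W_IE == 0))
})

test_that("recurrent pathways stay frozen through training", {
  f <- fix_net()
  tr <- run_training(f$net, f$stim, repetitions = 2)
  expect_identical(tr$net$W_EE, f$net$W_EE)
  expect_identical(tr$net$W_EI, f$net$W_EI)
  expect_identical(tr$net$W_IE, f$net$W_IE)
  expect_identical(tr$net$M_FF, f$net$M_FF)  # sparsity pattern fixed
})
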