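test_that("Hebbian rule: product form, mask, ceiling, closed form", {
  pl <- plasticity_params(eta_hebb = 0.01, w_ff_max = 1)
  W <- matrix(0.1, 3, 4)
  M <- matrix(TRUE, 3, 4); M[1, 1] <- FALSE
  W[!M] <- 0
  # zero pre- or postsynaptic calcium leaves weights unchanged
  expect_identical(hebbian_update(W, M, rep(0, 4), rep(1, 3), 1, pl), W)
  expect_identical(hebbian_update(W, M, rep(1, 4), rep(0, 3), 1, pl), W)
  # absent connections never appear
  W2 <- hebbian_update(W, M, rep(2, 4), rep(3, 3), 1, pl)
  expect_identical(W2[1, 1], 0)
  expect_true(all(W2[M] > W[M]))
  # constant calcium c over time T: increment = eta * c^2 * T / tau (to 1%)
  c0 <- 0.8; T <- 50; dt <- 0.025
  w <- matrix(0, 1, 1); m <- matrix(TRUE, 1, 1)
  for (i in seq_len(T / dt))
    w <- hebbian_update(w, m, c0, c0, dt, pl)
  expect_equal(w[1, 1], hebb_closed_form(c0, c0, T, pl$eta_hebb, pl$tau_hebb),
               tolerance = 0.01)
  # ceiling enforced
  pl2 <- plasticity_params(eta_hebb = 10, w_ff_max = 0.2)
  expect_true(all(hebbian_update(W, M, rep(5, 4), rep(5, 3), 10, pl2) <= 0.2))
  expect_error(hebbian_update(W, M, rep(-1, 4), rep(1, 3), 1, pl), ">= 0")
  expect_error(hebbian_update(W, M, rep(1, 5), rep(1, 3), 1, pl), "conform")
})

test_that("feedback rule: fixed point, direction, bounds", {
  pl <- plasticity_params(eta_fb = 0.1, w_fb_max = 1)
  w <- rep(0.5, 4)
  ca <- c(0.2, 0.2, 0.2, 0.2)
  # at the set-point nothing moves
  expect_identical(feedback_update(w, ca, 0.2, 1, pl), w)
  # above target: monotone growth until clipped at the ceiling
  traj <- Reduce(function(wk, i) feedback_update(wk, ca + 1, 0.2, 50, pl),
                 1:200, init = w, accumulate = TRUE)
  expect_true(all(diff(vapply(traj, `[`, numeric(1), 1)) >= 0))
  expect_equal(traj[[201]], rep(1, 4))
  # below target: decay, floored at zero
  w4 <- w
  for (i in 1:600) w4 <- feedback_update(w4, ca * 0, 0.2, 50, pl)
  expect_equal(w4, rep(0, 4))
  # per-neuron targets: only off-target entries move
  w5 <- feedback_update(w, c(0.2, 0.5, 0.2, 0.1), c(0.2, 0.2, 0.2, 0.2),
                        1, pl)
  expect_identical(w5[c(1, 3)], w[c(1, 3)])
  expect_gt(w5[2], w[2])
  expect_lt(w5[4], w[4])
  expect_error(feedback_update(w, ca[1:3], 0.2, 1, pl), "length")
})

test_that("calcium set-point is a running window mean", {
  expect_equal(update_calcium_target(rep(3, 100)), 3)
  x <- runif(50)
  expect_equal(update_calcium_target(x, dt = 2, window = 100), mean(x))
  # step trace 0 -> c at half-window: mean c/2 at window end
  step <- c(rep(0, 50), rep(2, 50))
  expect_equal(update_calcium_target(step, dt = 1, window = 100), 1)
  # trailing window only
  expect_equal(update_calcium_target(step, dt = 1, window = 50), 2)
  # matrix input: one set-point per row (per neuron)
  m <- rbind(rep(1, 10), rep(4, 10))
  expect_equal(update_calcium_target(m), c(1, 4))
  expect_error(update_calcium_target(numeric(0)), "empty")
})

test_that("compiled per-step plasticity matches the reference update", {
  f <- fix_net()
  net <- f$net
  st <- init_state(net)
  # seed calcium by hand; no neuron is near threshold so no spikes occur
  st$Ca_e1 <- seq(0.1, 1.2, length.out = net$n_v1_e)
  st$Ca_e2 <- seq(0.5, 1.6, length.out = net$n_v2_e)
  dt <- 0.025
  target <- rep(0.3, net$n_v2_e)
  out <- advance(net, st, NULL, duration = dt, dt = dt,
                 plastic_ff = TRUE, plastic_fb = TRUE, ca_target = target)
  # the compiled loop applies the rules with end-of-step calcium
  dec <- exp(-dt / net$params_e$tau_Ca)
  W_exp <- hebbian_update(net$W_FF, net$M_FF, st$Ca_e1 * dec,
                          st$Ca_e2 * dec, dt, net$plasticity)
  w_exp <- feedback_update(net$w_fb, st$Ca_e2 * dec, target, dt,
                           net$plasticity)
  expect_equal(out$net$W_FF, W_exp, tolerance = 1e-9)
  expect_equal(out$net$w_fb, w_exp, tolerance = 1e-9)
})

test_that("training potentiates selectively and within bounds", {
  f <- fix_net()
  tr <- run_training(f$net, f$stim, repetitions = 3)
  net <- tr$net
  pos <- neuron_positions(net$n_v1_e, net$n_v1_i, net$n_v2_e)
  cpos <- orientation_to_pos(f$stim$center, net$n_v1_e)
  d_pre <- ring_distance(pos$e1, cpos, net$n_v1_e)
  near <- which(d_pre <= 1.5)
  far <- which(d_pre >= 4)
  dW <- net$W_FF - f$net$W_FF
  expect_gt(max(dW[, near]), 0)
  expect_true(all(abs(dW[, far]) <= 0.01 * f$net$config$w_ff0))
  expect_true(all(net$W_FF <= net$plasticity$w_ff_max))
  expect_true(all(net$w_fb >= 0 & net$w_fb <= net$plasticity$w_fb_max))
  # repetitions = 0 leaves the network untouched
  tr0 <- run_training(f$net, f$stim, repetitions = 0)
  expect_identical(tr0$net$W_FF, f$net$W_FF)
  expect_identical(tr0$net$w_fb, f$net$w_fb)
})
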