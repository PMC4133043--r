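#' Baseline homeostatic calcium set-point
#'
#' Presents the (future) training stimulus to the naive network with
#' plasticity off and returns each V2 excitatory neuron's time-averaged
#' intracellular calcium — the per-neuron homeostatic set-point that the
#' feedback rule defends.  Computed once before training and then frozen.
#'
#' @param net a (calibrated) network.
#' @param stimulus a [stimulus_spec()].
#' @param duration averaging window (ms); default the stimulus duration.
#' @param dt integration step (ms).
#' @return numeric vector, one set-point per V2 neuron.
#' @export
baseline_calcium_target <- function(net, stimulus,
                                    duration = stimulus$duration,
                                    dt = 0.025) {
  out <- advance(net, init_state(net), stimulus_input(stimulus, net),
                 duration = duration, dt = dt)
  out$raw$mean_ca_v2_per_neuron
}

#' Train the network by repeated stimulus presentation
#'
#' Repeatedly presents `stimulus`; during each presentation both plasticity
#' rules integrate at every timestep (the Hebbian rule on feedforward
#' weights, the homeostatic rule on feedback weights).  Each presentation
#' starts from the resting state (the inter-stimulus blank is not simulated:
#' plasticity is driven by calcium, which is only nonzero during and briefly
#' after stimulation, and probing protocols always re-initialize state).
#'
#' @param net a calibrated network.
#' @param stimulus the training [stimulus_spec()].
#' @param repetitions number of presentations (>= 0).
#' @param ca_target per-neuron set-point from [baseline_calcium_target()];
#'   computed automatically if missing.
#' @param dt integration step (ms).
#' @param plastic_ff,plastic_fb enable each rule (defaults from
#'   `net$plasticity`).
#' @return list with `net` (trained), `ca_target` (the set-point used), and
#'   `history`: a data frame with one row per presentation (mean existing
#'   feedforward weight, mean feedback weight, mean feedback drive, mean V2
#'   calcium).
#' @export
run_training <- function(net, stimulus, repetitions, ca_target = NULL,
                         dt = 0.025,
                         plastic_ff = net$plasticity$ff_enabled,
                         plastic_fb = net$plasticity$fb_enabled) {
  if (repetitions < 0) stop("repetitions must be >= 0")
  if (is.null(ca_target))
    ca_target <- baseline_calcium_target(net, stimulus, dt = dt)
  hist <- data.frame(presentation = integer(0), mean_w_ff = numeric(0),
                     mean_w_fb = numeric(0), fb_drive = numeric(0),
                     mean_ca_v2 = numeric(0))
  if (repetitions == 0)
    return(list(net = net, ca_target = ca_target, history = hist))
  inp <- stimulus_input(stimulus, net)
  for (r in seq_len(repetitions)) {
    out <- tryCatch(
      advance(net, init_state(net), inp, duration = stimulus$duration,
              dt = dt, plastic_ff = plastic_ff, plastic_fb = plastic_fb,
              ca_target = ca_target),
      error = function(e) stop("training aborted at presentation ", r,
                               ": ", conditionMessage(e)))
    net <- out$net
    hist[r, ] <- list(r, mean(net$W_FF[net$M_FF]), mean(net$w_fb),
                      out$mean_fb_drive, out$mean_ca_v2)
  }
  list(net = net, ca_target = ca_target, history = hist)
}

#' Measure orientation tuning curves
#'
#' For each probe orientation, presents a bell stimulus (plasticity frozen,
#' state re-initialized to rest per probe — probing never trains) and
#' computes each requested neuron's time-averaged firing rate over the
#' final 80% of the stimulus window.
#'
#' @param net the network.
#' @param probe_orientations numeric vector of orientations (degrees).
#' @param probe_spec a [stimulus_spec()] template (its `center` is replaced
#'   by each probe).
#' @param neuron_ids V1 excitatory neurons to report (default all).
#' @param condition label stored with the curves (e.g. "before"/"after").
#' @param dt integration step (ms).
#' @return An object of class `tuning_set`: list with `rates` (matrix,
#'   neurons x probes), `probes`, `neuron_ids`, `condition`, and
#'   `fb_drive` (mean feedback drive per probe, for the feedback-strength
#'   profile).
#' @export
measure_tuning <- function(net, probe_orientations, probe_spec,
                           neuron_ids = seq_len(net$n_v1_e),
                           condition = "naive", dt = 0.025) {
  if (!length(probe_orientations)) stop("empty probe list")
  rates <- matrix(0, length(neuron_ids), length(probe_orientations),
                  dimnames = list(neuron_ids, probe_orientations))
  fb <- v2rate <- numeric(length(probe_orientations))
  for (k in seq_along(probe_orientations)) {
    sp <- probe_spec
    sp$center <- probe_orientations[k]
    out <- advance(net, init_state(net), stimulus_input(sp, net),
                   duration = sp$duration, dt = dt)
    r <- firing_rates(out$spikes$e1, net$n_v1_e, 0, sp$duration)
    rates[, k] <- r[neuron_ids]
    fb[k] <- out$mean_fb_drive
    v2rate[k] <- mean(firing_rates(out$spikes$e2, net$n_v2_e, 0,
                                   sp$duration))
  }
  structure(list(rates = rates, probes = probe_orientations,
                 neuron_ids = neuron_ids, condition = condition,
                 fb_drive = fb, mean_v2_rate = v2rate),
            class = "tuning_set")
}

#' Extract one neuron's tuning curve from a tuning set
#'
#' @param tuning a [measure_tuning()] result.
#' @param neuron_id a V1 excitatory neuron index present in the set.
#' @return An object of class `tuning_curve`: list with `orientation`,
#'   `rate`, `neuron_id`, `condition`.
#' @export
tuning_curve <- function(tuning, neuron_id) {
  row <- match(neuron_id, tuning$neuron_ids)
  if (is.na(row)) stop("neuron ", neuron_id, " not in the tuning set")
  structure(list(orientation = tuning$probes, rate = tuning$rates[row, ],
                 neuron_id = neuron_id, condition = tuning$condition),
            class = "tuning_curve")
}

#' Measure an f-I curve
#'
#' For each injected current value, runs the network with the background
#' stimulus driving it (so recurrent and feedback pathways are engaged, as
#' in probing a neuron that does not respond to the trained stimulus) while
#' injecting the current into the probed neuron, and records that neuron's
#' firing rate.  Plasticity frozen; state reset per current value.
#'
#' @param net the network.
#' @param neuron_id V1 excitatory neuron receiving the current.
#' @param current_values numeric vector of injected currents.
#' @param background a [stimulus_spec()] or `NULL` for none.
#' @param duration simulated time per current value (ms).
#' @param dt integration step (ms).
#' @return An object of class `fi_curve`: data frame with `current` and
#'   `rate` plus attributes `neuron_id`.
#' @export
probe_fi_curve <- function(net, neuron_id, current_values,
                           background = NULL, duration = 500, dt = 0.025) {
  base <- if (is.null(background))
    list(e1 = rep(0, net$n_v1_e), i1 = rep(0, net$n_v1_i),
         e2 = rep(0, net$n_v2_e))
  else stimulus_input(background, net)
  rate <- vapply(current_values, function(I) {
    inp <- base
    inp$e1[neuron_id] <- inp$e1[neuron_id] + I
    out <- advance(net, init_state(net), inp, duration = duration, dt = dt)
    firing_rates(out$spikes$e1, net$n_v1_e, 0, duration)[neuron_id]
  }, numeric(1))
  structure(data.frame(current = current_values, rate = rate),
            class = c("fi_curve", "data.frame"), neuron_id = neuron_id)
}

#' Decompose synaptic currents onto a V1 neuron
#'
#' Runs a stimulus presentation while recording the excitatory
#' (recurrent + feedback AMPA) and inhibitory (GABAa) synaptic currents
#' onto a neuron separately.  Besides the raw traces (at the momentary
#' membrane potential), reports the time-averaged components evaluated at
#' the resting-potential driving force — the quantity in which balanced
#' excitation and inhibition cancel ("shunting": large opposed conductances,
#' zero net current at rest).
#'
#' @param net the network.
#' @param neuron_id V1 excitatory neuron to record.
#' @param stimulus a [stimulus_spec()].
#' @param window portion of the simulation to average, as `c(t0, t1)` in
#'   ms; default the final 80% of the presentation.
#' @param dt integration step (ms).
#' @return list with `time`, `I_exc`, `I_inh`, `V` traces, and summary
#'   scalars `I_exc_rest`, `I_inh_rest` (time-averaged conductances times
#'   the rest driving forces), `g_exc`, `g_inh`.
#' @export
decompose_currents <- function(net, neuron_id, stimulus, window = NULL,
                               dt = 0.025) {
  dur <- stimulus$duration
  if (is.null(window)) window <- c(0.2 * dur, dur)
  if (window[1] < 0 || window[2] > dur || window[1] >= window[2])
    stop("window outside the simulated time span")
  out <- advance(net, init_state(net), stimulus_input(stimulus, net),
                 duration = dur, dt = dt, record = neuron_id,
                 record_every = 10L)
  tr <- out$traces
  keep <- tr$time >= window[1] & tr$time <= window[2]
  Vr <- resting_state(net$params_e, syn = net$syn)$V
  g_exc <- mean(tr$g_exc[keep, 1])
  g_inh <- mean(tr$g_inh[keep, 1])
  list(time = tr$time, I_exc = tr$I_exc[, 1], I_inh = tr$I_inh[, 1],
       V = tr$V[, 1],
       g_exc = g_exc, g_inh = g_inh,
       I_exc_rest = g_exc * (net$syn$V_ee - Vr),
       I_inh_rest = g_inh * (net$syn$V_ie - Vr),
       V_rest = Vr)
}

#' Effective input resistance at rest
#'
#' Slope of the steady subthreshold voltage response to small current steps
#' injected into a neuron while the network is driven by a background
#' stimulus.  Shunting inhibition (bigger balanced conductances) lowers
#' this slope — the model's electrophysiological signature of training.
#'
#' @param net the network.
#' @param neuron_id V1 excitatory neuron.
#' @param background a [stimulus_spec()] or `NULL`.
#' @param steps current steps (kept small and subthreshold).
#' @param duration per-step simulated time (ms); the voltage is averaged
#'   over the final 40%.
#' @param dt integration step (ms).
#' @return slope (mV per current unit).
#' @export
input_resistance <- function(net, neuron_id, background = NULL,
                             steps = c(-0.2, -0.1, 0, 0.1, 0.2),
                             duration = 300, dt = 0.025) {
  base <- if (is.null(background))
    list(e1 = rep(0, net$n_v1_e), i1 = rep(0, net$n_v1_i),
         e2 = rep(0, net$n_v2_e))
  else stimulus_input(background, net)
  vss <- vapply(steps, function(I) {
    inp <- base
    inp$e1[neuron_id] <- inp$e1[neuron_id] + I
    out <- advance(net, init_state(net), inp, duration = duration, dt = dt,
                   record = neuron_id, record_every = 10L)
    tr <- out$traces
    keep <- tr$time >= 0.6 * duration
    mean(tr$V[keep, 1])
  }, numeric(1))
  unname(stats::coef(stats::lm(vss ~ steps))[2])
}
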