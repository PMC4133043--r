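#' Tuning-curve metrics
#'
#' Quantifies one orientation tuning curve: amplitude (peak rate above the
#' spontaneous baseline), width (full width at half maximum above
#' baseline, in degrees), amplitude-to-width ratio `R = amplitude / width`,
#' preferred orientation (parabolically interpolated argmax) and the slope
#' at a reference orientation (central finite difference).  The orientation
#' axis is treated as circular with period 180 degrees.
#'
#' A curve with no response above `min_amplitude` yields `NA` metrics with
#' `responsive = FALSE` rather than zero-divided values.
#'
#' @param curve a [tuning_curve()], or any list with numeric `orientation`
#'   and `rate` of equal length.
#' @param reference_orientation where the slope is evaluated (degrees);
#'   default the trained/center orientation 90.
#' @param spontaneous baseline rate (Hz) subtracted before analysis
#'   (default 0: the deterministic network is silent without input).
#' @param min_amplitude smallest above-baseline peak (Hz) considered a
#'   response.
#' @return An object of class `tuning_metrics`: list with `amplitude`,
#'   `width`, `ratio_R`, `preferred`, `slope_at_reference`, `responsive`.
#' @export
tuning_metrics <- function(curve, reference_orientation = 90,
                           spontaneous = 0, min_amplitude = 1) {
  ori <- curve$orientation
  r <- pmax(0, curve$rate - spontaneous)
  n <- length(ori)
  if (n < 3) stop("tuning curve needs at least 3 probes")
  amp <- max(r)
  if (amp < min_amplitude) {
    return(structure(list(amplitude = NA_real_, width = NA_real_,
                          ratio_R = NA_real_, preferred = NA_real_,
                          slope_at_reference = NA_real_,
                          responsive = FALSE),
                     class = "tuning_metrics"))
  }
  pk <- which.max(r)
  nb <- function(i) ((i - 1) %% n) + 1  # circular index
  # preferred orientation: circular (double-angle) vector average of the
  # rates above half maximum — robust for plateau-topped curves, where an
  # interpolated argmax wobbles between grid points
  wts <- pmax(0, r - max(r) / 2)
  z <- sum(wts * exp(2i * ori * pi / 180))
  preferred <- if (Mod(z) > 0) (Arg(z) * 90 / pi) %% 180 else ori[pk]
  # full width at half maximum: walk out from the peak on both sides
  half <- amp / 2
  cross <- function(step) {
    i <- pk
    for (k in seq_len(n)) {
      j <- nb(i + step)
      if (r[j] < half) {
        # linear interpolation between grid points i and j
        f <- (r[i] - half) / (r[i] - r[j])
        return(abs(circ_diff(ori[i], ori[pk])) +
                 f * abs(circ_diff(ori[j], ori[i])))
      }
      i <- j
      if (j == pk) return(NA_real_)  # never drops below half: untuned
    }
    NA_real_
  }
  wl <- cross(-1L); wr <- cross(+1L)
  width <- wl + wr
  # slope at the reference orientation: symmetric finite difference
  k <- which.min(abs(circ_diff(ori, reference_orientation)))
  slope <- circ_slope(ori, r, k, nb)
  structure(list(amplitude = amp, width = width,
                 ratio_R = if (is.na(width) || width <= 0) NA_real_
                           else amp / width,
                 preferred = preferred, slope_at_reference = slope,
                 responsive = TRUE),
            class = "tuning_metrics")
}

# signed circular difference on the 180-degree orientation ring
circ_diff <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

circ_slope <- function(ori, r, k, nb) {
  kl <- nb(k - 1); kr <- nb(k + 1)
  (r[kr] - r[kl]) / (circ_diff(ori[kr], ori[kl]))
}

#' Classify a before/after tuning-curve change
#'
#' Implements the reduction-versus-sharpening dichotomy:
#' * `"reduction"` — amplitude and width both decreased while the slope at
#'   the reference orientation changed by no more than `slope_tolerance`
#'   (relatively): the curve scaled down without re-shaping.
#' * `"sharpening"` — the width decreased proportionally more than the
#'   amplitude and the slope magnitude at the reference orientation
#'   increased beyond tolerance: the curve got steeper around the trained
#'   orientation.
#' * `"none"` — neither (including no change).
#'
#' The slope change is normalized by the curve's characteristic slope
#' `amplitude_before / width_before` (rate per degree), not by the local
#' slope itself: at the peak of a near-symmetric curve the local slope is
#' close to zero and a ratio to it is ill-conditioned.
#'
#' @param before,after [tuning_metrics()] of the same neuron on the same
#'   probe grid.
#' @param slope_tolerance relative slope-change tolerance (default 0.15).
#' @param min_change smallest relative decrease counted as a change.
#' @return character: `"reduction"`, `"sharpening"` or `"none"`; `NA` with
#'   attribute `reason` if either side is unresponsive.
#' @export
classify_change <- function(before, after, slope_tolerance = 0.15,
                            min_change = 0.05) {
  if (!isTRUE(before$responsive) || !isTRUE(after$responsive)) {
    return(structure(NA_character_, reason = "unresponsive neuron"))
  }
  damp <- (before$amplitude - after$amplitude) / before$amplitude
  dwid <- (before$width - after$width) / before$width
  scale <- before$amplitude / before$width
  dslope <- (abs(after$slope_at_reference) -
               abs(before$slope_at_reference)) / scale
  if (dwid > min_change && dwid > damp + min_change &&
      dslope > slope_tolerance)
    return("sharpening")
  if (damp > min_change && dwid > min_change &&
      abs(dslope) <= slope_tolerance)
    return("reduction")
  "none"
}

#' Orientation-preference stability
#'
#' Checks, neuron by neuron, whether the preferred orientation moved by
#' more than `tolerance_deg` (circular distance) between two tuning sets.
#' Only neurons responsive in both conditions are judged.
#'
#' @param before,after [measure_tuning()] results on identical probe grids
#'   and neuron sets.
#' @param tolerance_deg tolerance (degrees); default one probe-grid step.
#' @return list with `table` (data frame: neuron, preferred before/after,
#'   stable flag), `fraction_stable`, `n_responsive`.
#' @export
preference_stability <- function(before, after, tolerance_deg = NULL) {
  stopifnot(identical(before$probes, after$probes),
            identical(before$neuron_ids, after$neuron_ids))
  if (is.null(tolerance_deg))
    tolerance_deg <- median(diff(sort(before$probes)))
  rows <- lapply(seq_along(before$neuron_ids), function(i) {
    mb <- tuning_metrics(tuning_curve(before, before$neuron_ids[i]))
    ma <- tuning_metrics(tuning_curve(after, after$neuron_ids[i]))
    resp <- isTRUE(mb$responsive) && isTRUE(ma$responsive)
    shift <- if (resp) abs(circ_diff(mb$preferred, ma$preferred)) else NA
    data.frame(neuron = before$neuron_ids[i],
               preferred_before = mb$preferred,
               preferred_after = ma$preferred,
               responsive = resp,
               stable = if (resp) shift <= tolerance_deg else NA)
  })
  tab <- do.call(rbind, rows)
  resp <- tab[tab$responsive, , drop = FALSE]
  list(table = tab,
       fraction_stable = if (nrow(resp)) mean(resp$stable) else NA_real_,
       n_responsive = nrow(resp))
}

#' Population response to one stimulus
#'
#' Rates of all V1 excitatory neurons evoked by a stimulus, optionally with
#' the recurrent V1 connections removed (feedback left intact).
#'
#' @param net the network.
#' @param stimulus a [stimulus_spec()].
#' @param with_recurrence keep the V1 recurrent pathways?
#' @param dt integration step.
#' @return numeric vector of rates (Hz), one per V1 excitatory neuron.
#' @export
population_response <- function(net, stimulus, with_recurrence = TRUE,
                                dt = 0.025) {
  if (!with_recurrence) net <- strip_recurrence(net)
  out <- advance(net, init_state(net), stimulus_input(stimulus, net),
                 duration = stimulus$duration, dt = dt)
  firing_rates(out$spikes$e1, net$n_v1_e, 0, stimulus$duration)
}

strip_recurrence <- function(net) {
  net$W_EE <- net$W_EE * 0
  net$W_EI <- net$W_EI * 0
  net$W_IE <- net$W_IE * 0
  net$W_II <- net$W_II * 0
  net
}

#' Input-output function of the center neuron
#'
#' Firing rate of the stimulus-center V1 neuron as a function of the
#' stimulus peak amplitude, with or without the recurrent V1 connections.
#' Recurrent interactions amplify strong responses and suppress weak ones,
#' so the with-recurrence curve crosses the without-recurrence curve from
#' below and contains an interior region of maximal slope (the region of
#' strong nonlinearity).
#'
#' @param net the network.
#' @param input_amplitudes increasing vector of stimulus peak amplitudes.
#' @param with_recurrence condition flag.
#' @param probe_spec [stimulus_spec()] template (center/width/duration).
#' @param dt integration step.
#' @return An object of class `io_function`: data frame with `input`,
#'   `rate` and attribute `with_recurrence`.
#' @export
io_function <- function(net, input_amplitudes, with_recurrence = TRUE,
                        probe_spec = stimulus_spec(), dt = 0.025) {
  if (!with_recurrence) net <- strip_recurrence(net)
  center_id <- which.min(abs(
    neuron_positions(net$n_v1_e, net$n_v1_i, net$n_v2_e)$e1 -
      orientation_to_pos(probe_spec$center, net$n_v1_e) %% net$n_v1_e))
  rate <- vapply(input_amplitudes, function(a) {
    sp <- probe_spec
    sp$amplitude <- a
    out <- advance(net, init_state(net), stimulus_input(sp, net),
                   duration = sp$duration, dt = dt)
    firing_rates(out$spikes$e1, net$n_v1_e, 0, sp$duration)[center_id]
  }, numeric(1))
  structure(data.frame(input = input_amplitudes, rate = rate),
            class = c("io_function", "data.frame"),
            with_recurrence = with_recurrence, neuron_id = center_id)
}

#' Feedback-drive profile across probe orientations
#'
#' Total feedback drive delivered to V1 (the sum over V2 neurons of
#' feedback weight times synaptic gating, time-averaged over the
#' presentation) as a function of the probe orientation.  Flat before
#' training; after training, peaked at the trained orientation and
#' decreasing with distance from it.
#'
#' @param net the network.
#' @param probe_orientations probe grid (degrees).
#' @param probe_spec a [stimulus_spec()] template.
#' @param dt integration step.
#' @return data frame with `orientation` and `fb_drive`.
#' @export
feedback_strength_profile <- function(net, probe_orientations,
                                      probe_spec = stimulus_spec(),
                                      dt = 0.025) {
  fb <- vapply(probe_orientations, function(o) {
    sp <- probe_spec
    sp$center <- o
    out <- advance(net, init_state(net), stimulus_input(sp, net),
                   duration = sp$duration, dt = dt)
    out$mean_fb_drive
  }, numeric(1))
  data.frame(orientation = probe_orientations, fb_drive = fb)
}
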