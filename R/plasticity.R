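#' Plasticity parameters
#'
#' Constants of the two learning rules.  The Hebbian rule grows each
#' existing feedforward weight with the product of pre- and postsynaptic
#' intracellular calcium on the 100 ms Hebbian time scale; the homeostatic
#' feedback rule moves each V2 neuron's (uniform fan-out) feedback weight
#' with the deviation of its calcium from a set-point on the 500 ms feedback
#' time scale.  Both rules carry a dimensionless gain (`eta_*`) setting how
#' much weight change a unit calcium signal produces per time-scale unit —
#' the calcium concentration is in arbitrary units, so the gains fix the
#' learning increment per presentation — and hard ceilings that bound the
#' pure-growth Hebbian rule.
#'
#' @param tau_hebb Hebbian time scale (ms).
#' @param tau_fb feedback-plasticity time scale (ms).
#' @param eta_hebb,eta_fb dimensionless learning gains.
#' @param w_ff_max,w_fb_max weight ceilings.
#' @param ff_enabled,fb_enabled pathway on/off flags.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(tau_hebb = 100, tau_fb = 500,
                              eta_hebb = 0.001, eta_fb = 0.012,
                              w_ff_max = 0.12, w_fb_max = 0.08,
                              ff_enabled = TRUE, fb_enabled = TRUE) {
  if (tau_hebb <= 0 || tau_fb <= 0) stop("time constants must be > 0")
  if (w_ff_max < 0 || w_fb_max < 0) stop("weight ceilings must be >= 0")
  structure(list(tau_hebb = tau_hebb, tau_fb = tau_fb,
                 eta_hebb = eta_hebb, eta_fb = eta_fb,
                 w_ff_max = w_ff_max, w_fb_max = w_fb_max,
                 ff_enabled = ff_enabled, fb_enabled = fb_enabled),
            class = "plasticity_params")
}

#' Hebbian update of the feedforward weights
#'
#' One Euler step of the calcium-product Hebbian rule on the existing
#' connections:
#' `W[i,j] <- min(W[i,j] + dt * eta * Ca_pre[j] * Ca_post[i] / tau_hebb,
#' w_ff_max)`.
#' Absent connections (mask zero) never appear.  This is the reference
#' implementation of the rule applied per integration step inside the
#' compiled simulator during training.
#'
#' @param W feedforward weight matrix (V2 x V1).
#' @param mask logical matrix of existing connections.
#' @param ca_pre calcium vector of V1 excitatory cells (length ncol).
#' @param ca_post calcium vector of V2 cells (length nrow).
#' @param dt step (ms).
#' @param params a [plasticity_params()].
#' @return Updated weight matrix.
#' @export
hebbian_update <- function(W, mask, ca_pre, ca_post, dt,
                           params = plasticity_params()) {
  if (length(ca_pre) != ncol(W) || length(ca_post) != nrow(W))
    stop("calcium vector lengths do not conform to the weight matrix")
  if (any(ca_pre < 0) || any(ca_post < 0))
    stop("calcium must be >= 0")
  dW <- dt * params$eta_hebb * outer(ca_post, ca_pre) / params$tau_hebb
  pmin(W + dW * mask, params$w_ff_max)
}

#' Homeostatic update of the feedback weights
#'
#' One Euler step of the feedback rule:
#' `w[i] <- clip(w[i] + dt * eta * (Ca_v2[i] - target) / tau_fb, 0,
#' w_fb_max)`.
#' Above-target V2 calcium strengthens the feedback, which (through
#' balanced excitation of V1 excitatory and inhibitory cells) shunts V1 and
#' lowers V2 drive — a stabilizing negative-feedback loop.
#'
#' @param w_fb feedback weight vector (one scalar per V2 neuron).
#' @param ca_v2 calcium vector of V2 cells.
#' @param target homeostatic calcium set-point: each V2 neuron's own
#'   baseline time-averaged calcium (scalar recycled).  A neuron whose
#'   calcium sits at its set-point (e.g. a silent neuron with a zero
#'   baseline) keeps its naive feedback weight.
#' @param dt step (ms).
#' @param params a [plasticity_params()].
#' @return Updated weight vector.
#' @export
feedback_update <- function(w_fb, ca_v2, target, dt,
                            params = plasticity_params()) {
  if (length(ca_v2) != length(w_fb))
    stop("calcium vector length does not match feedback weights")
  target <- rep_len(target, length(w_fb))
  w <- w_fb + dt * params$eta_fb * (ca_v2 - target) / params$tau_fb
  pmin(pmax(w, 0), params$w_fb_max)
}

#' Homeostatic calcium set-point from a baseline trace
#'
#' Running time-average of the (population-mean) V2 excitatory calcium over
#' the trailing `window`.  The set-point is computed once from a
#' pre-training baseline and then held fixed: a co-adapting target would
#' chase the training perturbation and cancel the learning signal.
#'
#' @param history numeric vector of calcium samples, evenly spaced — or a
#'   matrix with one row per V2 neuron (yielding one set-point per neuron).
#' @param dt sample spacing (ms).
#' @param window averaging window (ms); default the full history.
#' @return scalar set-point, or a vector (one per row of a matrix input).
#' @export
update_calcium_target <- function(history, dt = 1,
                                  window = NULL) {
  if (!length(history)) stop("calcium history is empty")
  if (is.matrix(history))
    return(apply(history, 1, update_calcium_target, dt = dt,
                 window = window))
  if (is.null(window)) window <- length(history) * dt
  k <- max(1L, min(length(history), round(window / dt)))
  mean(history[(length(history) - k + 1L):length(history)])
}
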