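#' Small deterministic test network
#'
#' A scaled-down architecture (default 10 excitatory + 3 inhibitory V1
#' neurons, 10 excitatory V2 neurons) with connectivity widths and drive
#' scaled to the ring size, for fast deterministic tests.  Same dynamics,
#' same code paths as the full model.
#'
#' @param seed seed for the feedforward sparsity draw.
#' @param n_v1_e,n_v1_i,n_v2_e population sizes.
#' @param ... further overrides passed to [connectivity_config()].
#' @return list with `net` (a [build_network()] result) and `stim` (a
#'   matched [stimulus_spec()] centered on the ring).
#' @export
small_network <- function(seed = 42L, n_v1_e = 10, n_v1_i = 3,
                          n_v2_e = 10, ...) {
  args <- utils::modifyList(
    list(n_v1_e = n_v1_e, n_v1_i = n_v1_i, n_v2_e = n_v2_e,
         recurrent_sd = 1.5, ff_sd = 1, ff_p_peak = 0.9,
         w_ei = 0.05,  # few interneurons: stronger per-cell E drive so the
                       # balance calibration has an inhibitory pathway
         seed = seed),
    list(...))
  cfg <- do.call(connectivity_config, args)
  net <- build_network(cfg)
  stim <- stimulus_spec(center = 90, amplitude = 3.5,
                        width = 0.06 * n_v1_e, duration = 300, to_i = 0.3)
  list(net = net, stim = stim)
}
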