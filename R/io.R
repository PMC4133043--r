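#' Default run configuration
#'
#' Single structured configuration covering every module: neuron and
#' synapse constants, connectivity, plasticity, protocol and analysis
#' settings, seed and integration step.  Defaults are the model's standard
#' values (conductances g_Le 0.05 / g_Li 0.1 / g_Na 100 / g_K 40 /
#' g_Ca 0.9 / g_AHP 0.05; reversals -65 / 55 / -80 / 120 mV; time constants
#' tau_Ca 100, tau_AMPA 2, tau_GABAa 2, tau_Hebb 100, tau_FB 500 ms;
#' populations 100/25/100; connectivity s.d. 10 and 5 neurons).
#'
#' @param ... overrides as nested named lists (unknown keys rejected).
#' @return An object of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    dt = 0.025,
    neuron_e = unclass(neuron_params("excitatory"))[
      setdiff(names(neuron_params("excitatory")), "class")],
    neuron_i = unclass(neuron_params("inhibitory"))[
      setdiff(names(neuron_params("inhibitory")), "class")],
    synapse = unclass(synapse_params()),
    connectivity = unclass(connectivity_config()),
    plasticity = unclass(plasticity_params()),
    ca_inc = 0.2,
    refrac = 2,
    protocol = list(
      train_center = 90, train_amplitude = 2, train_width = 6,
      train_duration = 500, train_to_i = 0, repetitions = 40,
      probe_step = 9, fi_currents = seq(0, 3, by = 0.5),
      fi_neuron_offset = 50),
    analysis = list(slope_tolerance = 0.15, min_amplitude = 1)
  )
  apply_overrides(cfg, list(...))
}

apply_overrides <- function(cfg, dots) {
  for (nm in names(dots)) {
    if (!nm %in% names(cfg))
      stop("unknown configuration key: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      bad <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown configuration key: ", nm, "$",
             paste(bad, collapse = ", "))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  do.call(neuron_params, c(list("excitatory"), cfg$neuron_e[
    setdiff(names(cfg$neuron_e), "has_ahp")]))
  do.call(synapse_params, cfg$synapse)
  cc <- cfg$connectivity
  cc$seed <- as.integer(cc$seed)
  do.call(connectivity_config, cc)
  do.call(plasticity_params, cfg$plasticity)
  if (cfg$dt <= 0 || cfg$dt > 0.05)
    stop("dt must lie in (0, 0.05] ms for the explicit integrator")
  structure(cfg, class = "run_config")
}

#' Load / save a run configuration (JSON)
#'
#' The configuration round-trips losslessly through JSON.  An empty file or
#' empty object yields all defaults; unknown keys are rejected with the
#' offending name.
#'
#' @param path file path.
#' @return [load_config()]: a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt)))
    jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  raw <- rapply(raw, function(x) x, how = "replace")
  cfg <- default_config()
  apply_overrides(unclass(cfg), as.list(raw))
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build the network described by a configuration
#'
#' @param config a [default_config()] result.
#' @return a [build_network()] network.
#' @export
network_from_config <- function(config) {
  cc <- config$connectivity
  cc$seed <- as.integer(cc$seed)
  build_network(
    do.call(connectivity_config, cc),
    params_e = do.call(neuron_params,
                       c(list("excitatory"),
                         config$neuron_e[setdiff(names(config$neuron_e),
                                                 c("has_ahp"))])),
    params_i = do.call(neuron_params,
                       c(list("inhibitory"),
                         config$neuron_i[setdiff(names(config$neuron_i),
                                                 c("has_ahp"))])),
    syn = do.call(synapse_params, config$synapse),
    plasticity = do.call(plasticity_params, config$plasticity),
    ca_inc = config$ca_inc, refrac = config$refrac)
}

#' Write simulation results to disk
#'
#' Spike trains, weight vectors/matrices and metric tables are written as
#' delimited text (CSV) plus a JSON sidecar holding the configuration echo
#' and its hash — plain-text, diff-friendly and language-portable.
#'
#' @param result a named list; data frames are written as `<name>.csv`,
#'   numeric vectors/matrices as CSV too, everything else into
#'   `meta.json`.
#' @param dir output directory (created if needed).
#' @param config optional `run_config` echoed into `meta.json`.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- list()
  for (nm in names(result)) {
    x <- result[[nm]]
    if (is.data.frame(x) || is.matrix(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(x), f, row.names = FALSE)
      files <- c(files, f)
    } else if (is.numeric(x) && length(x) > 1) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(data.frame(index = seq_along(x), value = x), f,
                       row.names = FALSE)
      files <- c(files, f)
    } else {
      meta[[nm]] <- x
    }
  }
  if (!is.null(config)) {
    meta$config <- unclass(config)
    meta$config_hash <- config_hash(config)
  }
  f <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, f))
}

#' @rdname write_results
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a complete experiment from a configuration
#'
#' Chains the stages of the standard workflow.  Commands:
#' * `"train"` — calibrate, baseline set-point, train; writes weight
#'   trajectories.
#' * `"tuning"` — before/after tuning sweeps and metric table.
#' * `"fi"` — before/after f-I curves of an off-stimulus neuron.
#' * `"decompose"` — before/after current decomposition at the center
#'   neuron.
#' * `"reproduce-figures"` — all of the above in sequence.
#'
#' Outputs are deterministic given the configuration (all randomness stems
#' from `config$connectivity$seed`).
#'
#' @param config a [default_config()].
#' @param command one of the commands above.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of in-memory results (also written to
#'   `out_dir`).
#' @export
run_experiment <- function(config = default_config(),
                           command = c("train", "tuning", "fi", "decompose",
                                       "reproduce-figures"),
                           out_dir = "results", quiet = FALSE) {
  command <- match.arg(command)
  say <- function(...) if (!quiet) message(sprintf(...))
  pr <- config$protocol
  stim <- stimulus_spec(pr$train_center, pr$train_amplitude,
                        pr$train_width, pr$train_duration, pr$train_to_i)
  t_all <- Sys.time()
  say("stage: build + calibrate")
  net0 <- network_from_config(config)
  cal <- calibrate_ei_balance(net0, stim)
  naive <- cal$net
  say("  I->E scale %.4g (balance residual %.3g)", cal$scale, cal$residual)
  res <- list(calibration = data.frame(scale = cal$scale,
                                       I_exc = cal$I_exc, I_inh = cal$I_inh))
  probes <- seq(0, 180 - pr$probe_step, by = pr$probe_step)
  say("stage: training (%d presentations)", pr$repetitions)
  tr <- run_training(naive, stim, pr$repetitions, dt = config$dt)
  res$training_history <- tr$history
  trained <- tr$net
  center_id <- round(orientation_to_pos(pr$train_center,
                                        naive$n_v1_e)) + 1L
  off_id <- ((center_id - 1 + pr$fi_neuron_offset) %% naive$n_v1_e) + 1L
  if (command %in% c("tuning", "reproduce-figures")) {
    say("stage: tuning sweeps (%d probes x 2)", length(probes))
    tb <- measure_tuning(naive, probes, stim, condition = "before",
                         dt = config$dt)
    ta <- measure_tuning(trained, probes, stim, condition = "after",
                         dt = config$dt)
    res$tuning_metrics <- tuning_metric_table(tb, ta, pr$train_center,
                                              config$analysis)
    res$fb_profile <- data.frame(orientation = probes,
                                 before = tb$fb_drive, after = ta$fb_drive)
  }
  if (command %in% c("fi", "reproduce-figures")) {
    say("stage: f-I probing (neuron %d)", off_id)
    fb <- probe_fi_curve(naive, off_id, pr$fi_currents, stim)
    fa <- probe_fi_curve(trained, off_id, pr$fi_currents, stim)
    res$fi_curves <- data.frame(current = fb$current, before = fb$rate,
                                after = fa$rate)
  }
  if (command %in% c("decompose", "reproduce-figures")) {
    say("stage: current decomposition (neuron %d)", center_id)
    db <- decompose_currents(naive, center_id, stim)
    da <- decompose_currents(trained, center_id, stim)
    res$currents <- data.frame(
      condition = c("before", "after"),
      I_exc_rest = c(db$I_exc_rest, da$I_exc_rest),
      I_inh_rest = c(db$I_inh_rest, da$I_inh_rest))
  }
  say("total wall time: %.1f s", as.numeric(Sys.time() - t_all, units = "secs"))
  write_results(res, out_dir, config)
  invisible(res)
}

#' Tidy metric table for a before/after tuning comparison
#'
#' @param before,after [measure_tuning()] results.
#' @param reference_orientation degrees.
#' @param analysis analysis settings (`slope_tolerance`, `min_amplitude`).
#' @return data frame with one row per neuron and condition: `neuron_id`,
#'   `condition`, `amplitude`, `width`, `R`, `slope`, `preferred`, plus the
#'   per-neuron `change` classification.
#' @export
tuning_metric_table <- function(before, after, reference_orientation = 90,
                                analysis = list(slope_tolerance = 0.15,
                                                min_amplitude = 1)) {
  rows <- lapply(before$neuron_ids, function(id) {
    mb <- tuning_metrics(tuning_curve(before, id), reference_orientation,
                         min_amplitude = analysis$min_amplitude)
    ma <- tuning_metrics(tuning_curve(after, id), reference_orientation,
                         min_amplitude = analysis$min_amplitude)
    cls <- classify_change(mb, ma, analysis$slope_tolerance)
    mk <- function(m, cond) data.frame(
      neuron_id = id, condition = cond, amplitude = m$amplitude,
      width = m$width, R = m$ratio_R, slope = m$slope_at_reference,
      preferred = m$preferred, change = as.character(cls))
    rbind(mk(mb, "before"), mk(ma, "after"))
  })
  do.call(rbind, rows)
}
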