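#' Define a surrogate-data case
#'
#' Surrogate targets are traces generated from a model with known ("true")
#' parameters, so that parameter recovery can be tested without external
#' recordings. Three cases are built in:
#'
#' * `uc1_hh`: a single 1000 ms voltage trace from the single-compartment
#'   Hodgkin-Huxley model (10 um diameter, 100 um length, original
#'   conductance densities 0.12 / 0.036 / 0.0003 S/cm2) under a 200 pA step
#'   from 200 to 700 ms; it contains 28 spikes at a 0 mV threshold.
#' * `uc2_synapse_vc`: the clamp current of the same compartment held at
#'   -70 mV while a double-exponential synapse (rise 0.3 ms, decay 3 ms,
#'   peak 10 nS = 0.01 uS, delay 2 ms) is driven by 4 input spikes at
#'   regular 100 ms intervals.
#' * `uc5_adexp_like`: four 1100 ms voltage traces of an adaptive
#'   exponential integrate-and-fire neuron (standard regular-spiking
#'   parameter set) at step amplitudes 0.30, 0.35, 0.40, 0.45 nA, sampled
#'   at 5 kHz; it exercises the multi-trace, multi-amplitude path.
#'
#' @param case_id One of `"uc1_hh"`, `"uc2_synapse_vc"`, `"uc5_adexp_like"`.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   recorded variable (mV or nA); 0 gives a deterministic target.
#' @param seed Seed for the noise generator.
#' @return An object of class `nf_surrogate_case`.
#' @export
surrogate_case <- function(case_id = c("uc1_hh", "uc2_synapse_vc",
                                       "uc5_adexp_like"),
                           noise_sd = 0, seed = 1L) {
  case_id <- match.arg(case_id)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  structure(list(case_id = case_id, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "nf_surrogate_case")
}

surrogate_defs <- function(case_id) {
  switch(case_id,
    uc1_hh = list(
      true_params = c(gna = 0.12, gk = 0.036, gl = 3e-4),
      backend = list(id = "hh_step", fixed = list(diam = 10, L = 100)),
      protocol = protocol_spec("current_clamp", "step", amplitudes = 0.2,
                               delay = 200, duration = 500, record = "v",
                               tstop = 1000, dt = 0.025, v_init = -65),
      parameters = list(parameter_spec("gna", 0, 1),
                        parameter_spec("gk", 0, 0.3),
                        parameter_spec("gl", 0, 0.003)),
      cost = cost_spec(c(mse_excl_spikes = 0.5, spike_count = 0.5),
                       spike_threshold = 0, exclusion_halfwidth = 5,
                       stim_window = c(200, 700))),
    uc2_synapse_vc = list(
      true_params = c(tau1 = 0.3, tau2 = 3, weight = 0.01, delay = 2),
      backend = list(id = "synaptic_vc",
                     fixed = list(spike_times = c(100, 200, 300, 400),
                                  hold_v = -70)),
      protocol = protocol_spec("voltage_clamp", "step", amplitudes = -70,
                               delay = 0, duration = 500, record = "i",
                               tstop = 500, dt = 0.025, v_init = -70),
      parameters = list(parameter_spec("tau1", 0.1, 5),
                        parameter_spec("tau2", 0.5, 10),
                        parameter_spec("weight", 0.001, 0.1),
                        parameter_spec("delay", 0.1, 10)),
      cost = cost_spec(c(mse = 1))),
    uc5_adexp_like = list(
      # plausible pyramidal-cell AdExpIF parameter set (synthetic; rheobase
      # just below 0.30 nA so the four amplitudes span ~10-30 Hz firing);
      # exercises the multi-trace, multi-amplitude path
      true_params = c(C = 0.2, gL = 0.012, EL = -70.6, VT = -50.4,
                      Vr = -58, tref = 2, deltaT = 2, a = 0.002,
                      b = 0.04, tauw = 120),
      backend = list(id = "adexp", fixed = list()),
      protocol = protocol_spec("current_clamp", "step",
                               amplitudes = c(0.30, 0.35, 0.40, 0.45),
                               delay = 100, duration = 900, record = "v",
                               tstop = 1100, dt = 0.2, v_init = -70.6),
      parameters = list(parameter_spec("C", 0.05, 0.5),
                        parameter_spec("gL", 0.005, 0.05),
                        parameter_spec("EL", -90, -60),
                        parameter_spec("VT", -60, -40),
                        parameter_spec("Vr", -90, -50),
                        parameter_spec("tref", 0.5, 10),
                        parameter_spec("deltaT", 0.5, 5),
                        parameter_spec("a", 0, 0.02),
                        parameter_spec("b", 0, 0.3),
                        parameter_spec("tauw", 20, 300)),
      cost = cost_spec(c(spike_count = 0.25, mse_excl_spikes = 0.25,
                         latency = 0.25, isi_diff = 0.25),
                       spike_threshold = -45, exclusion_halfwidth = 5,
                       stim_window = c(100, 1000))),
    stop("unknown surrogate case id '", case_id, "'"))
}

#' Generate a surrogate target and a ready-to-run configuration template
#'
#' Runs the case's built-in backend at the true parameters, optionally adds
#' seeded i.i.d. Gaussian noise to the recorded variable, and returns the
#' target trace set together with a configuration whose parameter bounds
#' bracket the true values. When `dir` is given, the trace file and the
#' configuration XML are written there (so the configuration passes
#' [read_config()] validation unmodified).
#'
#' @param case An [surrogate_case()] (or a case id string).
#' @param dir Optional directory to write `target_<case>.txt` and
#'   `config_<case>.xml` into.
#' @return A list with `target` ([nf_trace_set()]), `config`
#'   ([session_config()]), `true_params`, and (when `dir` is given) `paths`.
#' @export
make_surrogate <- function(case, dir = NULL) {
  if (is.character(case)) case <- surrogate_case(case)
  stopifnot(inherits(case, "nf_surrogate_case"))
  def <- surrogate_defs(case$case_id)
  backend <- get_backend(def$backend$id, def$backend$fixed)
  target <- backend$simulate(def$true_params, def$protocol)
  if (case$noise_sd > 0) {
    set.seed(case$seed)
    target$traces <- lapply(target$traces, function(tr) {
      tr$values <- tr$values + rnorm(length(tr$values), sd = case$noise_sd)
      tr
    })
  }
  kind <- target$traces[[1L]]$kind
  data <- list(path = paste0("target_", case$case_id, ".txt"), kind = kind,
               unit = canonical_unit(kind), dt = def$protocol$dt,
               n_traces = length(target))
  config <- session_config(
    data = data, backend = def$backend, parameters = def$parameters,
    protocol = def$protocol, cost = def$cost,
    optimizer = list(algorithm = "EO", seed = case$seed, pop_size = 100L,
                     generations = 100L),
    output_dir = "results")
  out <- list(target = target, config = config,
              true_params = def$true_params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tpath <- file.path(dir, data$path)
    write_traces(target, tpath)
    config$data$path <- tpath
    config$output_dir <- file.path(dir, "results")
    cpath <- file.path(dir, paste0("config_", case$case_id, ".xml"))
    write_config(config, cpath)
    out$config <- config
    out$paths <- list(target = tpath, config = cpath)
  }
  out
}
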