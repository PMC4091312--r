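#' Describe a stimulation and recording protocol
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param stim_kind `"step"` or `"custom_waveform"`.
#' @param amplitudes Step amplitudes: nA under current clamp, mV under
#'   voltage clamp; between 1 and 10 values.
#' @param delay Step onset, ms.
#' @param duration Step duration, ms.
#' @param waveform Optional [nf_trace()] giving a custom stimulus time
#'   course; it is re-sampled to the protocol `dt` via the standard
#'   alignment rules before injection.
#' @param record Recorded variable, `"v"` (mV) or `"i"` (nA).
#' @param tstop Simulation length, ms.
#' @param dt Integration / sampling step, ms.
#' @param v_init Initial voltage, mV.
#' @return An object of class `nf_protocol`.
#' @export
protocol_spec <- function(mode = c("current_clamp", "voltage_clamp"),
                          stim_kind = c("step", "custom_waveform"),
                          amplitudes = 0, delay = 0, duration = 0,
                          waveform = NULL, record = c("v", "i"),
                          tstop, dt = 0.025, v_init = -65) {
  mode <- match.arg(mode); stim_kind <- match.arg(stim_kind)
  record <- match.arg(record)
  if (stim_kind == "step" &&
      (length(amplitudes) < 1L || length(amplitudes) > 10L))
    stop("between 1 and 10 stimulus amplitudes are supported")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (delay + duration > tstop + 1e-9)
    stop("delay + duration must not exceed tstop")
  if (stim_kind == "custom_waveform" && is.null(waveform))
    stop("custom_waveform protocols need a 'waveform' trace")
  structure(list(mode = mode, stim_kind = stim_kind,
                 amplitudes = as.numeric(amplitudes), delay = delay,
                 duration = duration, waveform = waveform, record = record,
                 tstop = tstop, dt = dt, v_init = v_init),
            class = "nf_protocol")
}

#' Describe one tunable parameter
#'
#' @param name Parameter identifier.
#' @param lower,upper Finite bounds with `lower < upper`; bounds are
#'   mandatory for every tunable parameter.
#' @param initial Optional starting value inside the bounds.
#' @return An object of class `nf_param`.
#' @export
parameter_spec <- function(name, lower, upper, initial = NULL) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("parameter '", name, "': need finite lower < upper")
  if (!is.null(initial) && (initial < lower || initial > upper))
    stop("parameter '", name, "': initial value outside bounds")
  structure(list(name = as.character(name), lower = lower, upper = upper,
                 initial = initial),
            class = "nf_param")
}

# number of samples on the protocol grid
protocol_n <- function(protocol) floor(protocol$tstop / protocol$dt + 1e-9) + 1L

# stimulus vector sampled at protocol dt for one step amplitude (or the
# custom waveform, aligned to the protocol grid)
stimulus_vector <- function(protocol, amplitude) {
  n <- protocol_n(protocol)
  tt <- (seq_len(n) - 1) * protocol$dt
  if (protocol$stim_kind == "step") {
    amplitude * (tt >= protocol$delay & tt < protocol$delay + protocol$duration)
  } else {
    wf <- align_sampling(nf_trace_set(list(protocol$waveform)), protocol$dt)
    v <- approx(trace_times(wf$target$traces[[1L]]),
                wf$target$traces[[1L]]$values, xout = tt, rule = 2)$y
    v
  }
}

#' Built-in and external simulation backends
#'
#' `get_backend()` returns the backend contract for one of the built-in
#' simulators (`"hh_step"`, `"synaptic_vc"`, `"adexp"`) or the external
#' black-box wrapper (`"external"`): a list with `param_names` (the ordered
#' free parameters) and `simulate(params, protocol)` returning an
#' [nf_trace_set()] with one trace per stimulus amplitude, `dt` equal to the
#' protocol `dt` and length `floor(tstop/dt) + 1`.
#'
#' @param id Backend identifier.
#' @param fixed Named list of backend settings that are not optimized
#'   (geometry for `hh_step`; input spike times and holding level for
#'   `synaptic_vc`; fixed model parameters for `adexp`; the command line for
#'   `external`).
#' @return A backend contract list.
#' @export
get_backend <- function(id = c("hh_step", "synaptic_vc", "adexp", "external"),
                        fixed = list()) {
  id <- match.arg(id)
  switch(id,
    hh_step = list(
      id = id,
      param_names = c("gna", "gk", "gl"),
      simulate = function(params, protocol) {
        geom <- fixed[c("diam", "L")]
        if (is.null(geom$diam)) geom$diam <- 10
        if (is.null(geom$L)) geom$L <- 100
        simulate_hh_step(params, geometry = geom, protocol = protocol)
      }),
    synaptic_vc = list(
      id = id,
      param_names = c("tau1", "tau2", "weight", "delay"),
      simulate = function(params, protocol) {
        simulate_synaptic_vc(params,
                             spike_times = fixed$spike_times,
                             hold_v = if (is.null(fixed$hold_v))
                               protocol$amplitudes[1L] else fixed$hold_v,
                             protocol = protocol)
      }),
    adexp = list(
      id = id,
      param_names = c("C", "gL", "EL", "VT", "Vr", "tref", "deltaT",
                      "a", "b", "tauw"),
      simulate = function(params, protocol) {
        full <- modifyList(fixed, as.list(params))
        simulate_adexp(full, protocol)
      }),
    external = list(
      id = id,
      param_names = fixed$param_names,
      simulate = function(params, protocol) {
        run_external(fixed$command, params, protocol,
                     output_path = fixed$output_path,
                     args = fixed$args, timeout = fixed$timeout)
      }))
}

#' Simulate a single-compartment Hodgkin-Huxley model under current clamp
#'
#' A cylindrical compartment carrying the classical squid-axon Na+, K+ and
#' leak conductances at 6.3 degrees C (reversals 50, -77, -54.3 mV, specific
#' capacitance 1 uF/cm2). Numerics follow the standard staggered
#' compartmental-simulator scheme: an implicit (backward-Euler) voltage step
#' with frozen conductances alternating with analytic exponential updates of
#' the gating variables, whose steady states and time constants are read
#' from a 201-point rate table on \[-100, 100\] mV with linear
#' interpolation. Gating is initialized at steady state for `v_init`.
#'
#' @param params Named vector/list with conductance densities `gna`, `gk`,
#'   `gl` in S/cm2.
#' @param geometry Named list with `diam` and `L` in um; the membrane area
#'   is `pi * diam * L`.
#' @param protocol A current-clamp [protocol_spec()]; one voltage trace is
#'   produced per stimulus amplitude (nA).
#' @return An [nf_trace_set()] of voltage traces (mV) labelled with the
#'   stimulus amplitudes.
#' @examples
#' \donttest{
#' pr <- protocol_spec(amplitudes = 0.2, delay = 200, duration = 500,
#'                     tstop = 1000, dt = 0.025, v_init = -65)
#' ts <- simulate_hh_step(c(gna = 0.12, gk = 0.036, gl = 3e-4),
#'                        list(diam = 10, L = 100), pr)
#' nrow(detect_spikes(ts$traces[[1]], 0))  # 28
#' }
#' @export
simulate_hh_step <- function(params, geometry = list(diam = 10, L = 100),
                             protocol) {
  stopifnot(inherits(protocol, "nf_protocol"))
  if (protocol$mode != "current_clamp")
    stop("hh_step backend supports current clamp only")
  p <- as.list(params)
  for (nm in c("gna", "gk", "gl"))
    if (is.null(p[[nm]]) || p[[nm]] < 0)
      stop("hh_step needs nonnegative conductance '", nm, "'")
  if (geometry$diam <= 0 || geometry$L <= 0)
    stop("geometry must be positive")
  area <- pi * geometry$diam * geometry$L * 1e-8  # um2 -> cm2
  amps <- if (protocol$stim_kind == "step") protocol$amplitudes else 0
  traces <- lapply(amps, function(a) {
    istim <- stimulus_vector(protocol, a)
    v <- hh_core(p$gna, p$gk, p$gl, area, 1.0, 50, -77, -54.3,
                 protocol$v_init, protocol$dt, istim)
    nf_trace(v, "voltage", protocol$dt)
  })
  nf_trace_set(traces, amplitudes = if (protocol$stim_kind == "step") amps)
}

# HH steady-state ionic current (nA, outward positive) at a clamped voltage
hh_steady_current <- function(v, gna = 0.12, gk = 0.036, gl = 3e-4,
                              area_cm2 = pi * 10 * 100 * 1e-8) {
  am <- if (abs(v + 40) < 1e-6) 1 else 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20)
  bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- if (abs(v + 55) < 1e-6) 0.1 else 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  bn <- 0.125 * exp(-(v + 65) / 80)
  m <- am / (am + bm); h <- ah / (ah + bh); n <- an / (an + bn)
  # S/cm2 * mV = mA/cm2; * cm2 = mA; * 1e6 = nA
  (gna * m^3 * h * (v - 50) + gk * n^4 * (v + 77) + gl * (v + 54.3)) *
    area_cm2 * 1e6
}

#' Simulate a double-exponential conductance synapse under ideal voltage clamp
#'
#' The membrane is held ideally (zero series resistance) at `hold_v`; the
#' recorded trace is the clamp current in nA, outward positive. Each input
#' spike at time `t_sp` opens, after the synaptic `delay`, a conductance
#' `g(t) = weight * N * (exp(-(t - t_on)/tau2) - exp(-(t - t_on)/tau1))`
#' with `N` chosen so the peak conductance equals `weight` (the peak occurs
#' `tau1*tau2/(tau2 - tau1) * log(tau2/tau1)` after onset). The synaptic
#' reversal potential is 0 mV (excitatory); the holding current is the
#' steady-state ionic current of the clamped Hodgkin-Huxley compartment.
#'
#' @param params Named vector/list with `tau1` (rise, ms), `tau2` (decay,
#'   ms), `weight` (peak conductance, uS), `delay` (ms). A rise time at or
#'   above the decay time is clamped to `0.9999 * tau2`, mirroring the
#'   standard two-exponential synapse implementation.
#' @param spike_times Input spike times, ms.
#' @param hold_v Holding potential, mV.
#' @param protocol A voltage-clamp [protocol_spec()] with `record = "i"`.
#' @param cell Named list of the clamped compartment's properties
#'   (`gna`, `gk`, `gl` in S/cm2, `diam`, `L` in um).
#' @return An [nf_trace_set()] with one current trace (nA).
#' @export
simulate_synaptic_vc <- function(params, spike_times, hold_v = -70,
                                 protocol,
                                 cell = list(gna = 0.12, gk = 0.036,
                                             gl = 3e-4, diam = 10, L = 100)) {
  stopifnot(inherits(protocol, "nf_protocol"))
  if (protocol$mode != "voltage_clamp")
    stop("synaptic_vc backend supports voltage clamp only")
  p <- as.list(params)
  if (p$tau1 <= 0 || p$tau2 <= 0)
    stop("time constants must be positive")
  # like the reference simulator's two-exponential synapse, a rise time at
  # or above the decay time is clamped just below it, keeping the model
  # defined over overlapping optimization bounds
  if (p$tau1 > 0.9999 * p$tau2) p$tau1 <- 0.9999 * p$tau2
  n <- protocol_n(protocol)
  tt <- (seq_len(n) - 1) * protocol$dt
  area <- pi * cell$diam * cell$L * 1e-8
  i_hold <- hh_steady_current(hold_v, cell$gna, cell$gk, cell$gl, area)
  # peak-normalization factor of the double exponential
  tp <- p$tau1 * p$tau2 / (p$tau2 - p$tau1) * log(p$tau2 / p$tau1)
  N <- 1 / (exp(-tp / p$tau2) - exp(-tp / p$tau1))
  g <- numeric(n)
  for (ts in spike_times) {
    t_on <- ts + p$delay
    idx <- tt >= t_on
    u <- tt[idx] - t_on
    g[idx] <- g[idx] + p$weight * N * (exp(-u / p$tau2) - exp(-u / p$tau1))
  }
  i <- i_hold + g * (hold_v - 0)   # uS * mV = nA
  nf_trace_set(list(nf_trace(i, "current", protocol$dt)),
               amplitudes = hold_v)
}

#' Simulate the adaptive exponential integrate-and-fire model
#'
#' Integrates `C dV/dt = -gL (V - EL) + gL deltaT exp((V - VT)/deltaT) - w +
#' I(t)` and `tauw dw/dt = a (V - EL) - w` with fixed-step 4th-order
#' Runge-Kutta. When `V` reaches the numerical spike cutoff `V_cut = VT + 5
#' deltaT` (the crossing located by linear interpolation within the step),
#' the spike is drawn as a single sample at `V_cut`, `V` is reset to `Vr`
#' and clamped there for the refractory period `tref`, and `w` is
#' incremented by `b`. The exponential argument is capped at `(V_cut -
#' VT)/deltaT` for numerical safety.
#'
#' @param params Named vector/list with `C` (nF), `gL` (uS), `EL` (mV), `VT`
#'   (mV), `Vr` (mV), `tref` (ms), `deltaT` (mV), `a` (uS), `b` (nA), `tauw`
#'   (ms).
#' @param protocol A current-clamp [protocol_spec()]; one voltage trace per
#'   stimulus amplitude (nA).
#' @return An [nf_trace_set()] of voltage traces (mV).
#' @export
simulate_adexp <- function(params, protocol) {
  stopifnot(inherits(protocol, "nf_protocol"))
  if (protocol$mode != "current_clamp")
    stop("adexp backend supports current clamp only")
  p <- as.list(params)
  need <- c("C", "gL", "EL", "VT", "Vr", "tref", "deltaT", "a", "b", "tauw")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("adexp: missing parameter(s): ",
                         paste(miss, collapse = ", "))
  if (p$C <= 0 || p$gL <= 0 || p$tauw <= 0 || p$deltaT <= 0)
    stop("adexp: C, gL, tauw and deltaT must be positive")
  v0 <- if (is.null(protocol$v_init)) p$EL else protocol$v_init
  amps <- if (protocol$stim_kind == "step") protocol$amplitudes else 0
  traces <- lapply(amps, function(a) {
    istim <- stimulus_vector(protocol, a)
    res <- adexp_core(p$C, p$gL, p$EL, p$VT, p$Vr, p$tref, p$deltaT,
                      p$a, p$b, p$tauw, v0, 0, protocol$dt, istim)
    tr <- nf_trace(res$v, "voltage", protocol$dt)
    attr(tr, "spike_times") <- res$spike_times
    tr
  })
  nf_trace_set(traces, amplitudes = if (protocol$stim_kind == "step") amps)
}

#' Run an external black-box simulator
#'
#' The external program receives the parameter values appended to its
#' command line in declared order at full decimal precision, runs to
#' completion, and is expected to write the simulated trace set to
#' `output_path` in the plain-text trace dialect of [read_traces()] on the
#' protocol grid.
#'
#' @param command Path to the executable.
#' @param params Numeric parameter vector (appended in order).
#' @param protocol [protocol_spec()] describing the expected output (record
#'   kind, dt, number of traces = number of amplitudes).
#' @param output_path File the simulator writes its trace set to.
#' @param args Optional character vector of fixed arguments placed before
#'   the parameters.
#' @param timeout Seconds before the run is aborted (0 = no limit).
#' @return The simulator's output as an [nf_trace_set()].
#' @export
run_external <- function(command, params, protocol, output_path,
                         args = character(), timeout = 0) {
  if (is.null(timeout)) timeout <- 0
  argv <- c(args, sprintf("%.17g", as.numeric(params)))
  status <- suppressWarnings(
    system2(command, argv, stdout = FALSE, stderr = FALSE, timeout = timeout))
  if (!identical(status, 0L))
    stop("external simulator '", command, "' exited with status ", status)
  if (!file.exists(output_path))
    stop("external simulator '", command, "' did not write '", output_path, "'")
  kind <- if (protocol$record == "v") "voltage" else "current"
  tryCatch(
    read_traces(output_path, kind, canonical_unit(kind), protocol$dt,
                n_traces = max(1L, length(protocol$amplitudes))),
    error = function(e) stop("reading output of external simulator '",
                             command, "': ", conditionMessage(e)))
}
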