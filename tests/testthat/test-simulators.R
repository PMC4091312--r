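uc1_protocol <- function(dt = 0.025)
  protocol_spec("current_clamp", "step", amplitudes = 0.2, delay = 200,
                duration = 500, record = "v", tstop = 1000, dt = dt,
                v_init = -65)
uc1_params <- c(gna = 0.12, gk = 0.036, gl = 3e-4)

test_that("the HH compartment reproduces the published step response", {
  ts <- simulate_hh_step(uc1_params, list(diam = 10, L = 100), uc1_protocol())
  tr <- ts$traces[[1]]
  expect_equal(length(tr$values), 40001L)
  expect_equal(tr$dt, 0.025)
  expect_equal(nrow(detect_spikes(tr, 0)), 28L)
  # membrane voltage stays physiological
  expect_gt(min(tr$values), -100)
  expect_lt(max(tr$values), 60)
  expect_error(simulate_hh_step(uc1_params, list(diam = 10, L = 100),
                                protocol_spec("voltage_clamp", "step",
                                              amplitudes = -70, record = "i",
                                              tstop = 10)),
               "current clamp")
})

test_that("HH spike count is stable under dt refinement", {
  p1 <- detect_spikes(simulate_hh_step(uc1_params, list(diam = 10, L = 100),
                                       uc1_protocol(0.025))$traces[[1]], 0)
  p2 <- detect_spikes(simulate_hh_step(uc1_params, list(diam = 10, L = 100),
                                       uc1_protocol(0.0125))$traces[[1]], 0)
  expect_equal(nrow(p1), nrow(p2))
  # the onset of firing is grid-converged; late-spike phase drifts
  # cumulatively on this marginal limit cycle and is not asserted
  expect_lt(abs(p1$peak_t[1] - p2$peak_t[1]), 0.5)
})

test_that("HH with zero drive rests, and without sodium cannot overshoot 0 mV", {
  # resting steady state: initialize at the true rest and inject nothing
  v_rest <- uniroot(function(v) neurofitr:::hh_steady_current(v),
                    c(-80, -50), tol = 1e-12)$root
  pr <- uc1_protocol(); pr$amplitudes <- 0; pr$v_init <- v_rest
  tr <- simulate_hh_step(uc1_params, list(diam = 10, L = 100), pr)$traces[[1]]
  expect_equal(nrow(detect_spikes(tr, 0)), 0L)
  # the scheme settles onto its own (table-rate) equilibrium within ~1e-3
  # mV of the exact-rate rest, and is constant there
  expect_lt(max(abs(tr$values - v_rest)), 0.01)
  n <- length(tr$values)
  expect_lt(diff(range(tr$values[(n - 4000):n])), 1e-9)
  # terminal dV/dt below 1e-4 mV/ms after a step at default v_init
  tr2 <- simulate_hh_step(uc1_params, list(diam = 10, L = 100),
                          uc1_protocol())$traces[[1]]
  n <- length(tr2$values)
  expect_lt(abs(tr2$values[n] - tr2$values[n - 1]) / tr2$dt, 1e-4)
  # sodium-free membrane cannot reach the 0 mV detection threshold
  tr3 <- simulate_hh_step(c(gna = 0, gk = 0.036, gl = 3e-4),
                          list(diam = 10, L = 100), uc1_protocol())$traces[[1]]
  expect_equal(nrow(detect_spikes(tr3, 0)), 0L)
  expect_lt(max(tr3$values), 0)
})

test_that("HH trajectory matches an independent ODE solution sub-threshold", {
  skip_if_not_installed("deSolve")
  # weak stimulus keeps the membrane sub-threshold, where the staggered
  # scheme must agree with a high-accuracy continuous solution
  pr <- uc1_protocol(); pr$amplitudes <- 0.02; pr$tstop <- 300
  got <- simulate_hh_step(uc1_params, list(diam = 10, L = 100), pr)$traces[[1]]
  area <- pi * 10 * 100 * 1e-8
  rates <- function(v) {
    list(am = ifelse(abs(v + 40) < 1e-9, 1, 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))),
         bm = 4 * exp(-(v + 65) / 18),
         ah = 0.07 * exp(-(v + 65) / 20),
         bh = 1 / (1 + exp(-(v + 35) / 10)),
         an = ifelse(abs(v + 55) < 1e-9, 0.1, 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))),
         bn = 0.125 * exp(-(v + 65) / 80))
  }
  rhs <- function(t, y, parms) {
    r <- rates(y[1])
    i_ion <- 0.12 * y[2]^3 * y[3] * (y[1] - 50) + 0.036 * y[4]^4 * (y[1] + 77) +
      3e-4 * (y[1] + 54.3)
    i_stim <- if (t >= 200 && t < 700) 0.02 * 1e-6 / area else 0
    list(c(1000 * (-i_ion + i_stim),
           r$am - (r$am + r$bm) * y[2],
           r$ah - (r$ah + r$bh) * y[3],
           r$an - (r$an + r$bn) * y[4]))
  }
  r0 <- rates(-65)
  y0 <- c(-65, r0$am / (r0$am + r0$bm), r0$ah / (r0$ah + r0$bh),
          r0$an / (r0$an + r0$bn))
  sol <- deSolve::lsoda(y0, seq(0, 300, by = 0.025), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(sol[, 2] - got$values)), 0.05)
})

test_that("the clamped double-exponential synapse has the closed-form peak", {
  pr <- protocol_spec("voltage_clamp", "step", amplitudes = -70, delay = 0,
                      duration = 500, record = "i", tstop = 500, dt = 0.025,
                      v_init = -70)
  p <- c(tau1 = 0.3, tau2 = 3, weight = 0.01, delay = 2)
  ts <- simulate_synaptic_vc(p, spike_times = c(100, 200, 300, 400),
                             hold_v = -70, protocol = pr)
  tr <- ts$traces[[1]]
  expect_equal(tr$kind, "current")
  i_hold <- neurofitr:::hh_steady_current(-70)
  # deflection peak: conductance peak equals the weight, so the synaptic
  # current peaks at weight * (hold - 0) = -0.7 nA
  tp <- 0.3 * 3 / (3 - 0.3) * log(3 / 0.3)
  expect_equal(tp, 0.9 / 2.7 * log(10))
  tt <- trace_times(tr)
  # the grid need not sample the exact conductance peak; dt^2 curvature
  # error bounds the shortfall
  expect_lt(abs(min(tr$values) - (i_hold - 0.7)), 1e-4)
  # exactly 4 deflections, each starting at spike time + 2 ms delay
  dev <- abs(tr$values - i_hold) > 1e-4
  onsets <- tt[which(!dev[-length(dev)] & dev[-1]) + 1L]
  expect_equal(length(onsets), 4L)
  expect_equal(onsets, c(100, 200, 300, 400) + 2, tolerance = 0.06)
  # zero weight: constant holding current
  ts0 <- simulate_synaptic_vc(c(tau1 = 0.3, tau2 = 3, weight = 0, delay = 2),
                              spike_times = c(100, 200), hold_v = -70,
                              protocol = pr)
  expect_equal(diff(range(ts0$traces[[1]]$values)), 0)
  expect_error(simulate_synaptic_vc(c(tau1 = -1, tau2 = 3, weight = 0.01,
                                      delay = 2), 100, -70, pr), "positive")
  expect_error(simulate_synaptic_vc(p, 100, -70, uc1_protocol()),
               "voltage clamp")
})

test_that("the adaptive exponential neuron rests, charges like RC, and fires monotonically", {
  p <- c(C = 0.2, gL = 0.012, EL = -70.6, VT = -50.4, Vr = -58, tref = 2,
         deltaT = 2, a = 0.002, b = 0.04, tauw = 120)
  # I = 0 starting at (EL, 0): fixed point
  pr0 <- protocol_spec("current_clamp", "step", amplitudes = 0, delay = 0,
                       duration = 0, record = "v", tstop = 500, dt = 0.1,
                       v_init = p[["EL"]])
  tr0 <- simulate_adexp(p, pr0)$traces[[1]]
  # (EL, 0) is a fixed point up to the residual exponential term
  # gL*deltaT*exp((EL-VT)/deltaT), which at these values perturbs V by
  # well under 0.01 mV
  expect_lt(diff(range(tr0$values)), 0.01)
  expect_equal(nrow(detect_spikes(tr0, -45)), 0L)
  # a = b = 0 and tiny deltaT: sub-threshold step response approaches the
  # closed-form RC charging curve within 1%
  plin <- c(C = 0.2, gL = 0.012, EL = -70.6, VT = -30, Vr = -58, tref = 2,
            deltaT = 0.01, a = 0, b = 0, tauw = 120)
  pr1 <- protocol_spec("current_clamp", "step", amplitudes = 0.1, delay = 0,
                       duration = 500, record = "v", tstop = 500, dt = 0.05,
                       v_init = -70.6)
  tr1 <- simulate_adexp(plin, pr1)$traces[[1]]
  tt <- trace_times(tr1)
  vref <- -70.6 + (0.1 / 0.012) * (1 - exp(-tt * 0.012 / 0.2))
  sel <- vref < -45  # clearly below the exponential region
  expect_lt(max(abs(tr1$values[sel] - vref[sel]) / abs(vref[sel])), 0.01)
  # multi-amplitude protocol: one trace per amplitude, spike count
  # non-decreasing with drive, voltage never above V_cut
  pr2 <- protocol_spec("current_clamp", "step",
                       amplitudes = c(0.30, 0.35, 0.40, 0.45), delay = 100,
                       duration = 900, record = "v", tstop = 1100, dt = 0.2,
                       v_init = -70.6)
  ts <- simulate_adexp(p, pr2)
  expect_equal(length(ts), 4L)
  counts <- vapply(ts$traces, function(t) nrow(detect_spikes(t, -45)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[1], 0)
  vcut <- -50.4 + 5 * 2
  for (t in ts$traces) expect_lte(max(t$values), vcut + 1e-12)
  expect_error(simulate_adexp(p[-1], pr2), "missing parameter")
  expect_error(simulate_adexp(replace(p, "tauw", -1), pr2), "positive")
})

test_that("refractory clamp holds the reset voltage for tref after each spike", {
  p <- c(C = 0.2, gL = 0.012, EL = -70.6, VT = -50.4, Vr = -58, tref = 5,
         deltaT = 2, a = 0, b = 0, tauw = 120)
  pr <- protocol_spec("current_clamp", "step", amplitudes = 0.4, delay = 0,
                      duration = 400, record = "v", tstop = 400, dt = 0.1,
                      v_init = -70.6)
  tr <- simulate_adexp(p, pr)$traces[[1]]
  st <- attr(tr, "spike_times")
  expect_gt(length(st), 1)
  tt <- trace_times(tr)
  during <- tt > st[1] + 0.2 & tt < st[1] + 4.5
  expect_true(all(abs(tr$values[during] - (-58)) < 1e-9))
})

test_that("the black-box contract round-trips traces and surfaces failures", {
  dir <- withr::local_tempdir()
  out_file <- file.path(dir, "ext_out.txt")
  ref <- nf_trace_set(list(make_trace(sin(seq(0, 5, by = 0.05)) * 10 - 60,
                                      dt = 0.5)))
  ref_file <- file.path(dir, "ref.txt")
  write_traces(ref, ref_file)
  ok_cmd <- file.path(dir, "ok.sh")
  writeLines(c("#!/bin/sh", paste("cp", ref_file, out_file)), ok_cmd)
  Sys.chmod(ok_cmd, "0755")
  pr <- protocol_spec("current_clamp", "step", amplitudes = 0, record = "v",
                      tstop = 50, dt = 0.5, v_init = -60)
  got <- run_external(ok_cmd, c(0.1, 0.2), pr, out_file)
  expect_equal(got$traces[[1]]$values, ref$traces[[1]]$values,
               tolerance = 1e-8)
  # parameters are passed on the command line in order, full precision
  echo_cmd <- file.path(dir, "echo.sh")
  argf <- file.path(dir, "args.txt")
  writeLines(c("#!/bin/sh", paste0("echo \"$@\" > ", argf),
               paste("cp", ref_file, out_file)), echo_cmd)
  Sys.chmod(echo_cmd, "0755")
  run_external(echo_cmd, c(0.25, 1e-7), pr, out_file)
  expect_equal(scan(argf, quiet = TRUE), c(0.25, 1e-7))
  # failure modes: nonzero exit, no output, malformed output
  bad_cmd <- file.path(dir, "bad.sh")
  writeLines(c("#!/bin/sh", "exit 1"), bad_cmd)
  Sys.chmod(bad_cmd, "0755")
  expect_error(run_external(bad_cmd, 1, pr, out_file), "status 1")
  silent_cmd <- file.path(dir, "silent.sh")
  writeLines(c("#!/bin/sh", "true"), silent_cmd)
  Sys.chmod(silent_cmd, "0755")
  unlink(out_file)
  expect_error(run_external(silent_cmd, 1, pr, out_file), "did not write")
  wide_cmd <- file.path(dir, "wide.sh")
  writeLines(c("#!/bin/sh", paste0("printf '1 2\\n3 4\\n' > ", out_file)),
             wide_cmd)
  Sys.chmod(wide_cmd, "0755")
  expect_error(run_external(wide_cmd, 1, pr, out_file), "expected 1")
})

test_that("a user mapping hook composes with simulation as a pure function", {
  pr <- protocol_spec("current_clamp", "step", amplitudes = 0.2, delay = 50,
                      duration = 100, record = "v", tstop = 200, dt = 0.05,
                      v_init = -65)
  # abstract parameter: a single scale factor on the original densities
  map <- function(p) c(gna = 0.12, gk = 0.036, gl = 3e-4) * p[["scale"]]
  direct <- simulate_hh_step(map(c(scale = 0.9)), list(diam = 10, L = 100), pr)
  bk <- get_backend("hh_step", list(diam = 10, L = 100))
  via_hook <- bk$simulate(map(c(scale = 0.9)), pr)
  expect_identical(direct$traces[[1]]$values, via_hook$traces[[1]]$values)
})
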