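spec_all <- cost_spec(setNames(rep(1, length(cost_features)), cost_features),
                      spike_threshold = 0, exclusion_halfwidth = 3,
                      stim_window = c(10, 70), pptd_bins = 8)

test_that("forced-by-formula cost values come out exactly", {
  x <- make_trace(c(rep(-65, 50), rep(-55, 50)), 0.5)  # range 10
  s <- make_trace(x$values + 1, 0.5)
  expect_equal(pointwise_error("mse", s, x, spec_all), 0.01)
  # identity gives zero for every pointwise kind
  for (k in c("mse", "mse_excl_spikes", "deriv_diff"))
    expect_equal(pointwise_error(k, x, x, spec_all), 0)
  # spike count 28 vs 32 -> 4/61
  mk_spikes <- function(n) {
    v <- rep(-65, 2001)
    at <- round(seq(60, 1940, length.out = n))
    for (i in at) for (j in -3:3) v[i + j] <- max(v[i + j], 30 - 10 * abs(j))
    make_trace(v, 0.5)
  }
  t28 <- mk_spikes(28); t32 <- mk_spikes(32)
  expect_equal(spike_timing_error("spike_count", t32, t28, spec_all), 4 / 61)
  # both spikeless: the "plus one" case gives 0/1
  flat <- make_trace(rep(-65, 2001), 0.5)
  expect_equal(spike_timing_error("spike_count", flat, flat, spec_all), 0)
  # latency: first peaks at 210 vs 220 ms, duration 1000 ms
  one_at <- function(i) {
    v <- rep(-65, 2001)
    for (j in -3:3) v[i + j] <- 30 - 10 * abs(j)
    make_trace(v, 0.5)
  }
  expect_equal(spike_timing_error("latency", one_at(421), one_at(441), spec_all),
               (10 / 1000)^2)
  expect_equal(spike_timing_error("isi_diff", t28, t28, spec_all), 0)
})

test_that("traces differing only inside exclusion windows cost nothing sub-threshold", {
  set.seed(11)
  v <- random_spiky_trace(161, n_spikes = 2)
  x <- make_trace(v)
  sp <- detect_spikes(x, 0)
  v2 <- v
  tt <- trace_times(x)
  near <- abs(tt - sp$peak_t[1]) <= 1  # well inside the 3 ms half-width
  v2[near] <- v2[near] + 5
  s <- make_trace(v2)
  expect_equal(pointwise_error("mse_excl_spikes", s, x, spec_all), 0)
  expect_gt(pointwise_error("mse", s, x, spec_all), 0)
  # with no spikes in either trace the exclusion version equals plain mse
  set.seed(12)
  a <- make_trace(random_spiky_trace(161, n_spikes = 0))
  b <- make_trace(random_spiky_trace(161, n_spikes = 0))
  expect_equal(pointwise_error("mse_excl_spikes", a, b, spec_all),
               pointwise_error("mse", a, b, spec_all))
})

test_that("spike-shape errors follow their formulas on constructed pairs", {
  for (k in c("ap_overshoot", "ap_width", "ahp_depth")) {
    set.seed(13)
    v <- random_spiky_trace(161, n_spikes = 3)
    x <- make_trace(v)
    expect_equal(spike_shape_error(k, x, x, spec_all), 0)
  }
  # one paired spike, amplitudes 50 vs 40, max target amplitude 40
  mk <- function(height) {
    v <- rep(-60, 161)
    for (j in -4:4) v[80 + j] <- (height - 60) - abs(j) * 12
    make_trace(v)
  }
  s <- mk(110); x <- mk(100)  # amplitudes 50 and 40 above 0 mV
  expect_equal(spike_shape_error("ap_overshoot", s, x, spec_all),
               100 / 1600)
  # K = 0 with differing counts returns the maximal value 1
  flat <- make_trace(rep(-60, 161))
  expect_equal(spike_shape_error("ap_overshoot", flat, x, spec_all), 1)
  expect_equal(spike_shape_error("ap_width", flat, flat, spec_all), 0)
  # squared-mean vs mean-squared AHP readings differ in the expected
  # direction on noisy data
  set.seed(14)
  v1 <- random_spiky_trace(161, n_spikes = 3)
  v2 <- v1; v2[which(v1 < -58)] <- v2[which(v1 < -58)] - rnorm(sum(v1 < -58))
  spec_m <- cost_spec(c(ahp_depth = 1), spike_threshold = 0,
                      exclusion_halfwidth = 3, stim_window = c(10, 70),
                      ahp_mode = "mean_squared")
  a <- spike_shape_error("ahp_depth", make_trace(v2), make_trace(v1), spec_all)
  b <- spike_shape_error("ahp_depth", make_trace(v2), make_trace(v1), spec_m)
  expect_gte(b, a)  # mean of squares dominates square of mean
})

test_that("phase-plane density distance is a bounded metric-like score", {
  tt <- seq(0, 80, by = 0.5)
  s1 <- make_trace(sin(2 * pi * tt / 20) * 30 - 40)
  s2 <- make_trace(sin(2 * pi * tt / 11) * 30 - 40)
  expect_equal(pptd_error(s1, s1, spec_all), 0)
  d <- pptd_error(s1, s2, spec_all)
  expect_gt(d, 0); expect_lte(d, 1)
  # disjoint supports: maximal distance 1
  lo <- make_trace(rep(c(-80, -79), 40))
  hi <- make_trace(rep(c(20, 21), 40))
  expect_equal(pptd_error(hi, lo, spec_all), 1)
  # degenerate bounding box
  c1 <- make_trace(rep(-65, 80)); c2 <- make_trace(rep(-65, 80))
  expect_equal(pptd_error(c1, c2, spec_all), 0)
})

test_that("all eleven features agree with naive direct recomputation on random pairs", {
  set.seed(101)
  for (rep in 1:100) {
    s <- random_spiky_trace(161)
    x <- random_spiky_trace(161)
    ts <- make_trace(s); tx <- make_trace(x)
    for (f in cost_features) {
      got <- neurofitr:::eval_feature(f, ts, tx, spec_all)
      want <- naive_cost(f, s, x, 0.5, 0, 3, c(10, 70), 8)
      expect_rel_equal(got, want)
      expect_gte(got, 0)
      if (f %in% c("spike_count", "spike_count_stim", "pptd"))
        expect_lte(got, 1)
    }
  }
})

test_that("identity input scores zero on every feature", {
  set.seed(5)
  x <- make_trace(random_spiky_trace(161, n_spikes = 3))
  for (f in cost_features)
    expect_equal(neurofitr:::eval_feature(f, x, x, spec_all), 0)
})

test_that("weighted combination accumulates over pairs and normalizes weights", {
  set.seed(21)
  x1 <- make_trace(random_spiky_trace(161, 0)); s1 <- make_trace(x1$values + 1)
  x2 <- make_trace(random_spiky_trace(161, 0)); s2 <- make_trace(x2$values + 2)
  tgt <- nf_trace_set(list(x1, x2)); sim <- nf_trace_set(list(s1, s2))
  spec <- cost_spec(c(mse = 2, deriv_diff = 2))
  res <- combine_features(spec, sim, tgt)
  expect_equal(unname(res$weights), c(0.5, 0.5))
  m1 <- pointwise_error("mse", s1, x1, spec)
  m2 <- pointwise_error("mse", s2, x2, spec)
  expect_equal(unname(res$per_feature["mse"]), m1 + m2)
  expect_equal(res$total,
               0.5 * (m1 + m2) + 0.5 * res$per_feature[["deriv_diff"]])
  # convex combination bounds for a single pair
  one <- combine_features(spec, nf_trace_set(list(s1)), nf_trace_set(list(x1)))
  expect_lte(one$total, max(one$per_feature))
  expect_gte(one$total, min(one$per_feature))
  # identical sets cost zero
  expect_equal(combine_features(spec, tgt, tgt)$total, 0)
  # errors
  expect_error(combine_features(spec, nf_trace_set(list(s1)), tgt),
               "trace counts")
  expect_error(cost_spec(c(mse = -1)), "nonnegative")
  expect_error(cost_spec(c(nope = 1)), "unknown cost feature")
  expect_error(combine_features(cost_spec(c(mse = 0), normalize_weights = TRUE),
                                tgt, tgt), "all-zero")
  expect_error(spike_timing_error("spike_count_stim", s1, x1,
                                  cost_spec(c(spike_count_stim = 1))),
               "stim_window")
  expect_error(pointwise_error("mse", s1, make_trace(x1$values, dt = 0.25),
                               spec), "dt mismatch")
  expect_error(pointwise_error("mse", s1, make_trace(rep(0, 161)), spec),
               "range is zero")
})
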