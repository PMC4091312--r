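#' Feature identifiers of the available cost functions
#' @export
cost_features <- c("mse", "mse_excl_spikes", "deriv_diff", "spike_count",
                   "spike_count_stim", "isi_diff", "latency", "ap_overshoot",
                   "ap_width", "ahp_depth", "pptd")

#' Specify a weighted combination of cost functions
#'
#' A cost specification names the features entering the objective, their
#' weights, and the shared feature parameters (spike detection threshold,
#' spike exclusion window half-width, stimulus window, phase-plane grid
#' size). Each individual cost function is normalized so its values lie (at
#' least approximately) in `[0, 1]`; the weighted combination is accumulated
#' over the corresponding pairs of traces.
#'
#' @param terms Named numeric vector of nonnegative weights; names must be a
#'   subset of [cost_features].
#' @param spike_threshold Action-potential detection threshold, mV.
#' @param exclusion_halfwidth Half-width in ms of the window excluded around
#'   each spike peak by the sub-threshold error and by the sub-threshold
#'   range used to normalize the AHP feature.
#' @param stim_window `c(t_on, t_off)` in ms; required by
#'   `spike_count_stim`, optional elsewhere.
#' @param pptd_bins Number of bins per axis of the phase-plane histogram.
#' @param normalize_weights If `TRUE`, the weights are rescaled to sum to 1
#'   before combination.
#' @param ahp_mode `"squared_mean"` (the square of the mean difference in AHP
#'   depth; the default) or `"mean_squared"` (the mean of the squared
#'   differences).
#' @return An object of class `nf_cost_spec`.
#' @examples
#' cost_spec(c(mse_excl_spikes = 0.5, spike_count = 0.5),
#'           stim_window = c(200, 700))
#' @export
cost_spec <- function(terms, spike_threshold = 0, exclusion_halfwidth = 5,
                      stim_window = NULL, pptd_bins = 64,
                      normalize_weights = TRUE,
                      ahp_mode = c("squared_mean", "mean_squared")) {
  ahp_mode <- match.arg(ahp_mode)
  if (!length(terms) || is.null(names(terms)) || any(names(terms) == ""))
    stop("'terms' must be a named vector of weights")
  bad <- setdiff(names(terms), cost_features)
  if (length(bad))
    stop("unknown cost feature(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(cost_features, collapse = ", "))
  if (any(!is.finite(terms)) || any(terms < 0))
    stop("weights must be finite and nonnegative")
  if (!is.null(stim_window) && (length(stim_window) != 2L ||
                                stim_window[2L] < stim_window[1L]))
    stop("'stim_window' must be c(t_on, t_off) with t_on <= t_off")
  if (pptd_bins < 2) stop("'pptd_bins' must be at least 2")
  structure(list(terms = terms, spike_threshold = spike_threshold,
                 exclusion_halfwidth = exclusion_halfwidth,
                 stim_window = stim_window, pptd_bins = as.integer(pptd_bins),
                 normalize_weights = isTRUE(normalize_weights),
                 ahp_mode = ahp_mode),
            class = "nf_cost_spec")
}

# central-difference temporal derivative, one-sided at the ends (per ms)
trace_deriv <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  d
}

# logical mask of samples falling inside [peak - h, peak + h] around any
# spike peak of either trace; interval accumulation keeps this linear in
# the trace length rather than length x spike count
exclusion_mask <- function(tt, peaks, h) {
  n <- length(tt)
  if (!length(peaks)) return(rep(FALSE, n))
  t0 <- tt[1L]
  dt <- if (n > 1L) tt[2L] - tt[1L] else 1
  i1 <- pmax(1L, pmin(n + 1L, ceiling((peaks - h - t0) / dt - 1e-9) + 1L))
  i2 <- pmax(0L, pmin(n, floor((peaks + h - t0) / dt + 1e-9) + 1L))
  delta <- integer(n + 1L)
  keep <- i1 <= i2
  for (k in which(keep)) {
    delta[i1[k]] <- delta[i1[k]] + 1L
    delta[i2[k] + 1L] <- delta[i2[k] + 1L] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0L
}

#' Point-by-point trace errors
#'
#' * `mse`: mean squared difference of the two traces, normalized by the
#'   squared range of the target.
#' * `mse_excl_spikes`: the same mean restricted to the sub-threshold part of
#'   both traces, i.e. excluding samples within `exclusion_halfwidth` ms of
#'   any spike peak detected in either trace; the normalizing range is still
#'   that of the full target.
#' * `deriv_diff`: mean squared difference of the temporal derivatives
#'   (central differences, one-sided at the ends), normalized by the squared
#'   range of the target derivative.
#'
#' @param kind One of `"mse"`, `"mse_excl_spikes"`, `"deriv_diff"`.
#' @param sim,target Aligned [nf_trace()] objects of equal dt and length.
#' @param spec An [cost_spec()] supplying the spike threshold and exclusion
#'   half-width.
#' @return Nonnegative scalar error.
#' @export
pointwise_error <- function(kind = c("mse", "mse_excl_spikes", "deriv_diff"),
                            sim, target, spec = cost_spec(c(mse = 1))) {
  kind <- match.arg(kind)
  check_aligned(nf_trace_set(list(sim)), nf_trace_set(list(target)))
  s <- sim$values; x <- target$values
  if (kind == "deriv_diff") {
    s <- trace_deriv(s, sim$dt); x <- trace_deriv(x, target$dt)
  }
  rng <- max(x) - min(x)
  if (rng == 0) stop("target range is zero; normalized error undefined")
  if (kind == "mse_excl_spikes") {
    tt <- trace_times(target)
    peaks <- c(detect_spikes(sim, spec$spike_threshold)$peak_t,
               detect_spikes(target, spec$spike_threshold)$peak_t)
    keep <- !exclusion_mask(tt, peaks, spec$exclusion_halfwidth)
    if (!any(keep)) stop("all samples fall inside spike exclusion windows")
    mean((s[keep] - x[keep])^2) / rng^2
  } else {
    mean((s - x)^2) / rng^2
  }
}

#' Spike-timing errors
#'
#' * `spike_count`: absolute difference in the number of spikes, normalized
#'   by the sum of the two counts plus one (so two spikeless traces score 0).
#' * `spike_count_stim`: the same, counting only spikes whose peaks fall
#'   inside the stimulus window.
#' * `isi_diff`: sum of absolute differences between corresponding
#'   inter-spike intervals (spikes paired in order; extra spikes of the
#'   longer train ignored), normalized by the trace duration.
#' * `latency`: squared difference of the first-spike peak times, normalized
#'   by the squared trace duration; a spikeless trace contributes a latency
#'   equal to the trace duration, and the contribution is capped at 1.
#'
#' @inheritParams pointwise_error
#' @param kind One of `"spike_count"`, `"spike_count_stim"`, `"isi_diff"`,
#'   `"latency"`.
#' @return Nonnegative scalar error.
#' @export
spike_timing_error <- function(kind = c("spike_count", "spike_count_stim",
                                        "isi_diff", "latency"),
                               sim, target, spec = cost_spec(c(spike_count = 1))) {
  kind <- match.arg(kind)
  check_aligned(nf_trace_set(list(sim)), nf_trace_set(list(target)))
  th <- spec$spike_threshold
  ps <- detect_spikes(sim, th)$peak_t
  px <- detect_spikes(target, th)$peak_t
  T <- trace_duration(target)
  switch(kind,
    spike_count = abs(length(ps) - length(px)) / (length(ps) + length(px) + 1),
    spike_count_stim = {
      if (is.null(spec$stim_window))
        stop("spike_count_stim requires a stim_window in the cost spec")
      w <- spec$stim_window
      ns <- sum(ps >= w[1L] & ps <= w[2L])
      nx <- sum(px >= w[1L] & px <= w[2L])
      abs(ns - nx) / (ns + nx + 1)
    },
    isi_diff = {
      K <- min(length(ps), length(px)) - 1L
      if (K < 1L) 0 else
        sum(abs(diff(ps)[seq_len(K)] - diff(px)[seq_len(K)])) / T
    },
    latency = {
      t1s <- if (length(ps)) ps[1L] else T
      t1x <- if (length(px)) px[1L] else T
      min(1, (t1s - t1x)^2 / T^2)
    })
}

# sub-threshold voltage range of the target: range after removing the
# spike exclusion windows (0 if everything is excluded)
subthreshold_range <- function(target, spec) {
  tt <- trace_times(target)
  peaks <- detect_spikes(target, spec$spike_threshold)$peak_t
  keep <- !exclusion_mask(tt, peaks, spec$exclusion_halfwidth)
  if (!any(keep)) return(0)
  diff(range(target$values[keep]))
}

#' Spike-shape errors
#'
#' Spikes of the two traces are paired in order; `K = min(n_sim, n_target)`
#' pairs enter the average. If `K` is zero while the counts differ the
#' maximal value 1 is returned; if both traces are spikeless the error is 0.
#'
#' * `ap_overshoot`: mean squared difference of action-potential amplitudes
#'   (peak minus threshold), normalized by the squared maximal amplitude in
#'   the target.
#' * `ap_width`: mean squared difference of half-amplitude spike widths,
#'   normalized by the squared mean target width.
#' * `ahp_depth`: squared mean difference of after-hyperpolarization depths
#'   (or mean squared difference with `ahp_mode = "mean_squared"`),
#'   normalized by the squared sub-threshold voltage range of the target.
#'
#' @inheritParams pointwise_error
#' @param kind One of `"ap_overshoot"`, `"ap_width"`, `"ahp_depth"`.
#' @return Nonnegative scalar error.
#' @export
spike_shape_error <- function(kind = c("ap_overshoot", "ap_width", "ahp_depth"),
                              sim, target, spec = cost_spec(c(ap_overshoot = 1))) {
  kind <- match.arg(kind)
  check_aligned(nf_trace_set(list(sim)), nf_trace_set(list(target)))
  th <- spec$spike_threshold
  fs <- spike_features(sim, detect_spikes(sim, th), spec$stim_window)
  fx <- spike_features(target, detect_spikes(target, th), spec$stim_window)
  K <- min(nrow(fs), nrow(fx))
  if (K == 0L) return(if (nrow(fs) == nrow(fx)) 0 else 1)
  ks <- seq_len(K)
  switch(kind,
    ap_overshoot = mean((fs$amplitude[ks] - fx$amplitude[ks])^2) /
      max(fx$amplitude)^2,
    ap_width = mean((fs$width[ks] - fx$width[ks])^2) / mean(fx$width)^2,
    ahp_depth = {
      R <- subthreshold_range(target, spec)
      if (R == 0) return(0)
      d <- fs$ahp_depth[ks] - fx$ahp_depth[ks]
      if (spec$ahp_mode == "squared_mean") mean(d)^2 / R^2
      else mean(d^2) / R^2
    })
}

#' Phase-plane trajectory density error
#'
#' Each trace is mapped to its phase-plane point cloud `(V_i, dV/dt_i)`
#' (central differences). Both clouds are binned on a shared square grid
#' spanning their joint bounding box, each histogram is normalized to sum
#' to 1, and the total-variation distance `0.5 * sum |p - q|` is returned;
#' it is 0 for identical traces and at most 1.
#'
#' @inheritParams pointwise_error
#' @return Error in `[0, 1]`. A degenerate bounding box (a pair of constant
#'   traces) returns 0.
#' @export
pptd_error <- function(sim, target, spec = cost_spec(c(pptd = 1))) {
  check_aligned(nf_trace_set(list(sim)), nf_trace_set(list(target)))
  G <- spec$pptd_bins
  cloud <- function(tr) cbind(tr$values, trace_deriv(tr$values, tr$dt))
  cs <- cloud(sim); cx <- cloud(target)
  lo <- pmin(apply(cs, 2L, min), apply(cx, 2L, min))
  hi <- pmax(apply(cs, 2L, max), apply(cx, 2L, max))
  if (any(hi - lo == 0)) return(0)
  bin2 <- function(cl) {
    ix <- pmin(G, pmax(1L, 1L + floor((cl[, 1L] - lo[1L]) / (hi[1L] - lo[1L]) * G)))
    iy <- pmin(G, pmax(1L, 1L + floor((cl[, 2L] - lo[2L]) / (hi[2L] - lo[2L]) * G)))
    h <- tabulate((iy - 1L) * G + ix, nbins = G * G)
    h / sum(h)
  }
  0.5 * sum(abs(bin2(cs) - bin2(cx)))
}

# evaluate one feature on one pair of traces
eval_feature <- function(feature, sim, target, spec) {
  switch(feature,
    mse = , mse_excl_spikes = , deriv_diff =
      pointwise_error(feature, sim, target, spec),
    spike_count = , spike_count_stim = , isi_diff = , latency =
      spike_timing_error(feature, sim, target, spec),
    ap_overshoot = , ap_width = , ahp_depth =
      spike_shape_error(feature, sim, target, spec),
    pptd = pptd_error(sim, target, spec),
    stop("unknown cost feature: ", feature))
}

#' Weighted combination of cost functions over a pair of trace sets
#'
#' For each feature the per-pair values are accumulated (summed) over the
#' corresponding pairs of traces; the total is the weighted sum of the
#' accumulated feature values, with the weights first rescaled to sum to 1
#' when `spec$normalize_weights` is set.
#'
#' @param spec An [cost_spec()].
#' @param sim,target [nf_trace_set()] objects with equal trace counts,
#'   sampling steps and lengths.
#' @return A list with elements `total` (scalar), `per_feature` (named
#'   vector of accumulated raw feature values) and `weights` (the effective
#'   weights used).
#' @export
combine_features <- function(spec, sim, target) {
  stopifnot(inherits(spec, "nf_cost_spec"))
  check_aligned(sim, target)
  w <- spec$terms
  if (spec$normalize_weights) {
    if (sum(w) == 0) stop("cannot normalize an all-zero weight vector")
    w <- w / sum(w)
  }
  per <- setNames(numeric(length(w)), names(w))
  for (f in names(w)) {
    per[f] <- sum(vapply(seq_along(sim$traces), function(i)
      eval_feature(f, sim$traces[[i]], target$traces[[i]], spec), numeric(1)))
  }
  list(total = sum(w * per), per_feature = per, weights = w)
}
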