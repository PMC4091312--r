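# Naive, loop-based re-computations of every cost function straight from its
# formula, plus generators for small randomized trace pairs. These stay
# independent of the vectorized implementations in the package.

naive_detect <- function(v, tt, thr) {
  spikes <- list()
  open <- v[1] >= thr
  onset <- if (open) 1L else NA_integer_
  for (i in 2:length(v)) {
    if (!open && v[i - 1] < thr && v[i] >= thr) {
      open <- TRUE; onset <- i
    } else if (open && v[i - 1] >= thr && v[i] < thr) {
      seg <- onset:(i - 1)
      pk <- seg[which.max(v[seg])]
      spikes[[length(spikes) + 1]] <- list(onset = onset, peak = pk,
                                           offset = i - 1)
      open <- FALSE
    }
  }
  if (open) {
    seg <- onset:length(v)
    pk <- seg[which.max(v[seg])]
    spikes[[length(spikes) + 1]] <- list(onset = onset, peak = pk,
                                         offset = length(v))
  }
  spikes
}

naive_deriv <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i == 1) (v[2] - v[1]) / dt
    else if (i == n) (v[n] - v[n - 1]) / dt
    else (v[i + 1] - v[i - 1]) / (2 * dt)
  }
  d
}

naive_in_window <- function(t, peaks_t, h) {
  for (p in peaks_t) if (t >= p - h && t <= p + h) return(TRUE)
  FALSE
}

# per-spike features mirroring the stated definitions: amplitude relative to
# the detection threshold, width at half amplitude with linear
# interpolation, AHP depth from spike offset to the next onset (last spike:
# to stimulus end or trace end)
naive_features <- function(v, tt, thr, stim_window = NULL) {
  sp <- naive_detect(v, tt, thr)
  out <- list()
  t_end <- if (is.null(stim_window)) tt[length(tt)]
           else min(stim_window[2], tt[length(tt)])
  for (k in seq_along(sp)) {
    s <- sp[[k]]
    amp <- v[s$peak] - thr
    half <- thr + amp / 2
    i1 <- s$peak
    while (i1 > 1 && v[i1 - 1] >= half) i1 <- i1 - 1
    i2 <- s$peak
    while (i2 < length(v) && v[i2 + 1] >= half) i2 <- i2 + 1
    tl <- if (i1 > 1) tt[i1 - 1] + (half - v[i1 - 1]) / (v[i1] - v[i1 - 1]) *
      (tt[i1] - tt[i1 - 1]) else tt[1]
    tr <- if (i2 < length(v)) tt[i2] + (half - v[i2]) / (v[i2 + 1] - v[i2]) *
      (tt[i2 + 1] - tt[i2]) else tt[length(v)]
    w0 <- tt[s$offset]
    w1 <- if (k < length(sp)) tt[sp[[k + 1]]$onset] else max(t_end, w0)
    sel <- which(tt >= w0 - 1e-9 & tt <= w1 + 1e-9)
    out[[k]] <- list(peak_t = tt[s$peak], amp = amp, width = tr - tl,
                     ahp = if (length(sel)) thr - min(v[sel]) else 0)
  }
  out
}

naive_cost <- function(feature, s, x, dt, thr, h, stim_window, bins,
                       ahp_mode = "squared_mean") {
  n <- length(x)
  tt <- (seq_len(n) - 1) * dt
  T <- (n - 1) * dt
  rng <- max(x) - min(x)
  fs <- naive_features(s, tt, thr, stim_window)
  fx <- naive_features(x, tt, thr, stim_window)
  ps <- vapply(fs, `[[`, numeric(1), "peak_t")
  px <- vapply(fx, `[[`, numeric(1), "peak_t")
  if (feature == "mse") {
    acc <- 0
    for (i in 1:n) acc <- acc + (s[i] - x[i])^2
    return(acc / n / rng^2)
  }
  if (feature == "mse_excl_spikes") {
    acc <- 0; m <- 0
    for (i in 1:n)
      if (!naive_in_window(tt[i], c(ps, px), h)) {
        acc <- acc + (s[i] - x[i])^2; m <- m + 1
      }
    return(acc / m / rng^2)
  }
  if (feature == "deriv_diff") {
    ds <- naive_deriv(s, dt); dx <- naive_deriv(x, dt)
    acc <- 0
    for (i in 1:n) acc <- acc + (ds[i] - dx[i])^2
    return(acc / n / (max(dx) - min(dx))^2)
  }
  if (feature == "spike_count")
    return(abs(length(ps) - length(px)) / (length(ps) + length(px) + 1))
  if (feature == "spike_count_stim") {
    ns <- sum(ps >= stim_window[1] & ps <= stim_window[2])
    nx <- sum(px >= stim_window[1] & px <= stim_window[2])
    return(abs(ns - nx) / (ns + nx + 1))
  }
  if (feature == "isi_diff") {
    K <- min(length(ps), length(px)) - 1
    if (K < 1) return(0)
    acc <- 0
    for (k in 1:K) acc <- acc + abs((ps[k + 1] - ps[k]) - (px[k + 1] - px[k]))
    return(acc / T)
  }
  if (feature == "latency") {
    t1s <- if (length(ps)) ps[1] else T
    t1x <- if (length(px)) px[1] else T
    return(min(1, (t1s - t1x)^2 / T^2))
  }
  if (feature %in% c("ap_overshoot", "ap_width", "ahp_depth")) {
    K <- min(length(fs), length(fx))
    if (K == 0) return(if (length(fs) == length(fx)) 0 else 1)
    if (feature == "ap_overshoot") {
      acc <- 0
      for (k in 1:K) acc <- acc + (fs[[k]]$amp - fx[[k]]$amp)^2
      return(acc / K / max(vapply(fx, `[[`, numeric(1), "amp"))^2)
    }
    if (feature == "ap_width") {
      acc <- 0
      for (k in 1:K) acc <- acc + (fs[[k]]$width - fx[[k]]$width)^2
      return(acc / K / mean(vapply(fx, `[[`, numeric(1), "width"))^2)
    }
    # ahp_depth: sub-threshold range of the target (its own spike windows
    # removed) as the normalizer
    keep <- !vapply(tt, naive_in_window, logical(1), peaks_t = px, h = h)
    if (!any(keep)) return(0)
    R <- max(x[keep]) - min(x[keep])
    if (R == 0) return(0)
    dsum <- 0; d2sum <- 0
    for (k in 1:K) {
      dd <- fs[[k]]$ahp - fx[[k]]$ahp
      dsum <- dsum + dd; d2sum <- d2sum + dd^2
    }
    return(if (ahp_mode == "squared_mean") (dsum / K)^2 / R^2
           else d2sum / K / R^2)
  }
  if (feature == "pptd") {
    ds <- naive_deriv(s, dt); dx <- naive_deriv(x, dt)
    lo1 <- min(min(s), min(x)); hi1 <- max(max(s), max(x))
    lo2 <- min(min(ds), min(dx)); hi2 <- max(max(ds), max(dx))
    if (hi1 == lo1 || hi2 == lo2) return(0)
    hist2 <- function(vv, dd) {
      hmat <- matrix(0, bins, bins)
      for (i in 1:n) {
        ix <- min(bins, max(1, 1 + floor((vv[i] - lo1) / (hi1 - lo1) * bins)))
        iy <- min(bins, max(1, 1 + floor((dd[i] - lo2) / (hi2 - lo2) * bins)))
        hmat[ix, iy] <- hmat[ix, iy] + 1
      }
      hmat / sum(hmat)
    }
    return(0.5 * sum(abs(hist2(s, ds) - hist2(x, dx))))
  }
  stop("unknown feature in naive oracle: ", feature)
}

# a short random voltage-like trace: smooth baseline plus a few triangular
# spikes poking above 0 mV
random_spiky_trace <- function(n = 161, dt = 0.5, n_spikes = sample(0:4, 1)) {
  tt <- (seq_len(n) - 1) * dt
  v <- -60 + 5 * sin(2 * pi * tt / runif(1, 20, 60)) + rnorm(n, sd = 0.5)
  if (n_spikes > 0) {
    at <- sort(sample(10:(n - 10), n_spikes))
    for (i in at) {
      hgt <- runif(1, 70, 100)
      w <- sample(2:4, 1)
      for (j in -w:w)
        v[i + j] <- max(v[i + j], v[i] + hgt * (1 - abs(j) / (w + 0.5)))
    }
  }
  v
}

make_trace <- function(v, dt = 0.5, kind = "voltage") nf_trace(v, kind, dt)

expect_rel_equal <- function(got, want, tol = 1e-12) {
  denom <- max(abs(want), 1e-300)
  if (want == 0) expect_lt(abs(got), 1e-12)
  else expect_lt(abs(got - want) / denom, tol)
}
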