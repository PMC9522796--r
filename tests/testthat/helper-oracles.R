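# Independent brute-force oracles, deliberately written as literal loops so
# they share no code path with the implementation they check.

# literal PeakCaller-style enumerator: every local maximum of the smoothed
# trace is tested against the threshold and the rise/fall criteria by
# explicit scanning loops
oracle_peaks <- function(dff_vec, rise_pct = 20, fall_pct = 15,
                         lookback = 30, lookahead = 25,
                         sg_window = 9, sg_order = 3, alpha = 0.05) {
  n <- length(dff_vec)
  sm <- signal::sgolayfilt(dff_vec, p = sg_order, n = sg_window)
  # forward EMA by loop
  fwd <- numeric(n); fwd[1] <- dff_vec[1]
  for (t in 2:n) fwd[t] <- alpha * dff_vec[t] + (1 - alpha) * fwd[t - 1]
  bwd <- numeric(n); bwd[n] <- dff_vec[n]
  for (t in (n - 1):1) bwd[t] <- alpha * dff_vec[t] + (1 - alpha) * bwd[t + 1]
  trend <- (fwd + bwd) / 2
  thr <- mean(dff_vec) + sd(dff_vec)
  out <- NULL
  for (p in 2:(n - 1)) {
    if (!(sm[p] > sm[p - 1] && sm[p] >= sm[p + 1])) next
    if (!(sm[p] > thr)) next
    h <- sm[p] - trend[p]
    if (h <= 0) next
    rise_level <- sm[p] - rise_pct / 100 * h
    onset <- NA
    for (j in (p - 1):max(1, p - lookback)) {
      if (sm[j] <= rise_level) { onset <- j; break }   # nearest = last below
    }
    if (is.na(onset)) next
    fall_level <- sm[p] - fall_pct / 100 * h
    decay_end <- NA
    found <- FALSE
    if (p < n) {
      for (j in (p + 1):min(n, p + lookahead)) {
        if (sm[j] <= fall_level) { decay_end <- j; found <- TRUE; break }
      }
    }
    if (!found && p + lookahead <= n) next   # full window seen, no fall
    amp <- -Inf   # raw-trace maximum within half a smoothing window
    for (j in max(1, p - sg_window %/% 2):min(n, p + sg_window %/% 2))
      if (dff_vec[j] > amp) amp <- dff_vec[j]
    out <- rbind(out, data.frame(peak_frame = p, onset_frame = onset,
                                 decay_end_frame = decay_end,
                                 amplitude = amp))
  }
  if (is.null(out))
    data.frame(peak_frame = integer(), onset_frame = integer(),
               decay_end_frame = integer(), amplitude = numeric())
  else out
}

# elementwise Pearson correlation from the covariance definition
oracle_cor_matrix <- function(m) {
  k <- ncol(m)
  out <- matrix(1, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- m[, i]; y <- m[, j]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# double-loop Euclidean pair distances
oracle_distances <- function(x, y) {
  n <- length(x)
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    out <- c(out, sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2))
  out
}

# noise-free dF/F0 by per-frame re-computation of the windowed mean
oracle_dff <- function(raw, window = 60, alignment = "trailing") {
  n <- length(raw)
  out <- numeric(n)
  for (t in seq_len(n)) {
    if (alignment == "trailing") {
      w <- raw[max(1, t - window + 1):t]
    } else {
      half <- window %/% 2
      w <- raw[max(1, t - half):min(n, t + (window - half - 1))]
    }
    out[t] <- (raw[t] - mean(w)) / mean(w)
  }
  out
}

# build a raw trace (baseline 100) containing planted unit-peak transients
planted_trace <- function(n, onsets, amp = 0.5, rise = 1.5, decay = 4,
                          noise_sd = 0, baseline = 100) {
  kern <- tgcalcium:::transient_kernel(n, rise, decay, 1)
  act <- numeric(n)
  for (t0 in onsets) {
    seg <- t0:n
    act[seg] <- act[seg] + amp * kern[seq_along(seg)]
  }
  pmax(baseline * (1 + act) + rnorm(n, 0, noise_sd * baseline), 1e-3)
}
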