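test_that("dF/F0 of a constant trace is identically zero", {
  d <- compute_dff(rep(42, 100))
  expect_equal(d$f0, rep(42, 100))
  expect_equal(d$dff, rep(0, 100))
})

test_that("dF/F0 recovers a known relative elevation", {
  # hold the trace window-constant, then raise it by k over a segment long
  # after the window has settled: dff = (f - f0)/f0 there
  raw <- rep(100, 200)
  d <- compute_dff(raw * 1, window_frames = 60)
  expect_equal(d$dff, rep(0, 200))
  k <- 0.3
  raw2 <- c(rep(100, 150), rep(100 * (1 + k), 50))
  d2 <- compute_dff(raw2, window_frames = 60, alignment = "trailing")
  # at the step frame the trailing 60-frame window holds 59 baseline
  # frames plus the elevated one; dff follows from the definition
  f0_151 <- (59 * 100 + 100 * (1 + k)) / 60
  expect_equal(d2$dff[151], (100 * (1 + k) - f0_151) / f0_151,
               tolerance = 1e-12)
})

test_that("dF/F0 matches a per-frame brute-force recomputation", {
  set.seed(99)
  raw <- abs(rnorm(120, 100, 8)) + 1
  for (al in c("trailing", "centered")) {
    d <- compute_dff(raw, window_frames = 60, alignment = al)
    expect_equal(d$dff, oracle_dff(raw, 60, al), tolerance = 1e-12)
  }
})

test_that("dF/F0 rejects invalid input", {
  expect_error(compute_dff(rep(1, 10), window_frames = 60), "shorter")
  expect_error(compute_dff(c(rep(1, 99), 0)), "positive")
})

test_that("firing thresholds follow their definitions", {
  expect_equal(firing_threshold(rep(0, 50), "mean_plus_sd"), 0)
  expect_equal(firing_threshold(rep(0, 50), "ten_sem"), 0)
  set.seed(1)
  z <- rnorm(100)
  x <- 0.1 + 0.05 * (z - mean(z)) / sd(z)   # mean .1, sd .05 exactly
  expect_equal(firing_threshold(x, "mean_plus_sd"), 0.15)
  expect_equal(firing_threshold(x, "ten_sem"), 10 * 0.05 / sqrt(100))
})

test_that("a flat trace yields no events", {
  expect_equal(nrow(detect_peaks(compute_dff(rep(10, 100)))), 0)
})

test_that("a single planted transient is parametrized correctly", {
  raw <- planted_trace(200, onsets = 60, amp = 0.5)
  ev <- detect_peaks(compute_dff(raw))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude - 0.5), 0.1 * 0.5)
  # oracle: criterion crossing times read directly off the planted kernel
  kern <- 0.5 * tgcalcium:::transient_kernel(141, 1.5, 4, 1)
  pk <- which.max(kern)
  h <- max(kern)
  onset_k <- max(which(kern[1:(pk - 1)] <= max(kern) - 0.2 * h))
  decay_k <- pk + min(which(kern[(pk + 1):141] <= max(kern) - 0.15 * h))
  expect_lte(abs(ev$peak_frame - (59 + pk)), 1)
  expect_lte(abs(ev$rise_s - (pk - onset_k)), 1)
  expect_lte(abs(ev$decay_s - (decay_k - pk)), 1)
})

test_that("two well-separated transients give two events at their frames", {
  raw <- planted_trace(260, onsets = c(50, 150), amp = 0.5)
  ev <- detect_peaks(compute_dff(raw))
  expect_equal(nrow(ev), 2)
  kern_peak <- which.max(tgcalcium:::transient_kernel(100, 1.5, 4, 1))
  expect_lte(abs(ev$peak_frame[1] - (49 + kern_peak)), 1)
  expect_lte(abs(ev$peak_frame[2] - (149 + kern_peak)), 1)
})

test_that("peak detection is invariant to positive rescaling of dF/F0", {
  set.seed(7)
  dff <- oracle_dff(planted_trace(150, c(30, 90), noise_sd = 0.03))
  a <- detect_peaks(dff)
  b <- detect_peaks(5 * dff)
  expect_equal(a$peak_frame, b$peak_frame)
  expect_equal(a$onset_frame, b$onset_frame)
  expect_equal(a$decay_end_frame, b$decay_end_frame)
  expect_equal(5 * a$amplitude, b$amplitude, tolerance = 1e-12)
})

test_that("every reported event exceeds the firing threshold", {
  set.seed(13)
  for (rep in 1:10) {
    raw <- planted_trace(200, onsets = sample(20:170, 3), noise_sd = 0.05)
    d <- compute_dff(raw)
    ev <- detect_peaks(d)
    if (nrow(ev) > 0) {
      sm <- signal::sgolayfilt(d$dff, p = 3, n = 9)
      expect_true(all(sm[ev$peak_frame] > d$threshold))
    }
  }
})

test_that("detection matches the literal brute-force enumerator", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(80:200, 1)
    raw <- planted_trace(n, onsets = sample(10:(n - 20), sample(0:4, 1)),
                         amp = runif(1, 0.2, 0.8), noise_sd = 0.05)
    d <- compute_dff(raw)
    got <- detect_peaks(d)
    want <- oracle_peaks(d$dff)
    expect_equal(got$peak_frame, want$peak_frame)
    expect_equal(got$onset_frame, want$onset_frame)
    expect_equal(got$decay_end_frame, want$decay_end_frame)
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-10)
  }
})

test_that("event recovery is sensitive and precise at SNR 5", {
  set.seed(77)
  tp <- fp <- fn <- 0
  for (rep in 1:40) {
    onsets <- sort(sample(seq(20, 530, by = 40), 8))
    raw <- planted_trace(600, onsets, amp = 0.5, noise_sd = 0.1)
    ev <- detect_peaks(compute_dff(raw))
    kern_peak <- which.max(tgcalcium:::transient_kernel(50, 1.5, 4, 1))
    expected <- onsets + kern_peak - 1
    hit <- rep(FALSE, length(expected))
    for (p in ev$peak_frame) {
      j <- which.min(abs(expected - p))
      if (abs(expected[j] - p) <= 3 && !hit[j]) hit[j] <- TRUE else fp <- fp + 1
    }
    tp <- tp + sum(hit); fn <- fn + sum(!hit)
  }
  expect_gte(tp / (tp + fn), 0.9)   # sensitivity
  expect_gte(tp / (tp + fp), 0.9)   # precision
})

test_that("rasters mark onset-to-decay spans and sum to event durations", {
  ev0 <- detect_peaks(compute_dff(rep(5, 100)))
  expect_true(all(build_raster(ev0, roi_ids = 1:3, n_frames = 100) == 0))

  ev <- data.frame(roi_id = 2, peak_frame = 15, onset_frame = 10,
                   decay_end_frame = 20, amplitude = 1, rise_s = 5,
                   decay_s = 5, duration_s = 10)
  r <- build_raster(ev, roi_ids = 1:3, n_frames = 40)
  expect_equal(which(r["2", ] == 1), 10:20)
  expect_true(all(r["1", ] == 0) && all(r["3", ] == 0))

  set.seed(3)
  raw <- planted_trace(300, onsets = c(40, 140, 240), noise_sd = 0.02)
  d <- compute_dff(raw, roi_id = 7)
  ev2 <- detect_peaks(d)
  r2 <- build_raster(ev2, roi_ids = 7, n_frames = 300)
  expect_equal(sum(r2),
               sum(ev2$decay_end_frame - ev2$onset_frame + 1))
})

test_that("active counts are per block with their mean", {
  ev <- data.frame(roi_id = c(1, 1, 2, 3), peak_frame = c(50, 320, 100, 310),
                   onset_frame = c(45, 315, 95, 305),
                   decay_end_frame = c(55, 325, 105, 315),
                   amplitude = 1, rise_s = 5, decay_s = 5, duration_s = 10)
  a <- count_active(ev)
  expect_equal(unname(a$per_block), c(2L, 2L))
  expect_equal(a$mean_active, 2)
  # a neuron with events only in block 1 is not counted in block 2
  expect_false(2 %in% ev$roi_id[ev$peak_frame > 300])

  none <- count_active(detect_peaks(compute_dff(rep(5, 600))))
  expect_equal(none$mean_active, 0)
})

test_that("a planted depolarising epoch drives every neuron's response", {
  cfg <- small_cfg(n_neurons = 10, frac_active = 0.5, high_k_start_frame = 120,
                   n_frames = 150, noise_sd = 0.02, seed = 25)
  sim <- simulate_movie(cfg)
  nrn <- sim$truth$neurons
  rois <- roi_set_from_circles(nrn[, c("centroid_x_um", "centroid_y_um")],
                               nrn$diameter_um, c(100, 100),
                               sim$movie$pixel_size_um, ids = nrn$id)
  tr <- extract_traces(sim$movie, rois)
  dffs <- detect_events_all(tr)$dff
  hk <- high_k_response(dffs, epoch = c(120, 150))
  expect_equal(hk$pct_responding, 100)
  # all-zero traces give an all-zero heatmap
  flat <- list(a = compute_dff(rep(10, 150)), b = compute_dff(rep(3, 150)))
  hk0 <- high_k_response(flat, epoch = c(120, 150))
  expect_true(all(hk0$heatmap == 0))
})

test_that("the 10*SEM rule flags at least the mean+SD responders", {
  cfg <- small_cfg(n_neurons = 10, frac_active = 0.5, high_k_start_frame = 120,
                   n_frames = 150, noise_sd = 0.05, seed = 26)
  sim <- simulate_movie(cfg)
  nrn <- sim$truth$neurons
  rois <- roi_set_from_circles(nrn[, c("centroid_x_um", "centroid_y_um")],
                               nrn$diameter_um, c(100, 100),
                               sim$movie$pixel_size_um, ids = nrn$id)
  dffs <- detect_events_all(extract_traces(sim$movie, rois))$dff
  hk_sem <- high_k_response(dffs, epoch = c(120, 150), rule = "ten_sem")
  hk_msd <- high_k_response(dffs, epoch = c(120, 150), rule = "mean_plus_sd")
  for (id in names(dffs)) {
    t_sem <- firing_threshold(dffs[[id]], "ten_sem")
    t_msd <- firing_threshold(dffs[[id]], "mean_plus_sd")
    if (t_sem < t_msd)
      expect_gte(hk_sem$responds[id], hk_msd$responds[id])
  }
})
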