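#' Compute sliding-window dF/F0
#'
#' The baseline F0 at each frame is the mean raw fluorescence over a
#' 60-frame sliding window (truncated at the trace edges) and
#' `dff[t] = (raw[t] - f0[t]) / f0[t]`. The default alignment is
#' `trailing` (causal: the window ends at t); `centered` places the window
#' symmetrically around t.
#'
#' @param raw numeric trace of positive raw intensities.
#' @param window_frames sliding-window length in frames (default 60).
#' @param alignment `"trailing"` (default) or `"centered"`.
#' @param roi_id optional id carried through to outputs.
#' @param threshold_rule rule used by [firing_threshold()]:
#'   `"mean_plus_sd"` (default) or `"ten_sem"`.
#' @return object of class `DffTrace`: `roi_id`, `raw`, `f0`, `dff`,
#'   `threshold`, `threshold_rule`.
#' @export
compute_dff <- function(raw, window_frames = 60,
                        alignment = c("trailing", "centered"),
                        roi_id = NA_integer_,
                        threshold_rule = c("mean_plus_sd", "ten_sem")) {
  alignment <- match.arg(alignment)
  threshold_rule <- match.arg(threshold_rule)
  n <- length(raw)
  if (n < window_frames)
    stop("trace shorter than the baseline window")
  if (any(raw <= 0))
    stop("raw trace must be strictly positive for a dF/F0 baseline")
  cs <- c(0, cumsum(raw))
  idx <- seq_len(n)
  if (alignment == "trailing") {
    lo <- pmax(idx - window_frames + 1, 1)
    hi <- idx
  } else {
    half <- window_frames %/% 2
    lo <- pmax(idx - half, 1)
    hi <- pmin(idx + (window_frames - half - 1), n)
  }
  f0 <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  dff <- (raw - f0) / f0
  out <- structure(list(roi_id = roi_id, raw = raw, f0 = f0, dff = dff,
                        threshold = NA_real_,
                        threshold_rule = threshold_rule),
                   class = "DffTrace")
  out$threshold <- firing_threshold(dff, threshold_rule)
  out
}

#' Firing threshold for a dF/F0 trace
#'
#' Two conventions: `mean_plus_sd` (mean(dff) + sd(dff); used for
#' spontaneous-activity rasters and correlation analysis) and `ten_sem`
#' (10 * sd(dff)/sqrt(n); used for the high-potassium binary heatmaps).
#' Statistics are computed over the whole trace.
#'
#' @param dff numeric dF/F0 trace (or a `DffTrace`).
#' @param rule `"mean_plus_sd"` or `"ten_sem"`.
#' @return the threshold, a single number in dF/F0 units.
#' @export
firing_threshold <- function(dff, rule = c("mean_plus_sd", "ten_sem")) {
  rule <- match.arg(rule)
  if (inherits(dff, "DffTrace")) dff <- dff$dff
  n <- length(dff)
  if (n < 2) stop("need at least 2 frames")
  switch(rule,
         mean_plus_sd = mean(dff) + stats::sd(dff),
         ten_sem = 10 * stats::sd(dff) / sqrt(n))
}

# two-sided exponential moving average: mean of a forward and a backward
# first-order EMA with smoothing factor alpha
two_sided_ema <- function(x, alpha) {
  fwd <- stats::filter(alpha * x, 1 - alpha, method = "recursive",
                       init = x[1])
  bwd <- rev(stats::filter(alpha * rev(x), 1 - alpha, method = "recursive",
                           init = x[length(x)]))
  as.numeric(fwd + bwd) / 2
}

#' Detect and parametrize calcium transients
#'
#' PeakCaller-style detection on a dF/F0 trace. The trace is smoothed with
#' a Savitzky-Golay filter; an underlying trendline is computed as a
#' two-sided exponential moving average. A local maximum of the smoothed
#' trace qualifies as a transient iff (a) its smoothed value exceeds the
#' firing threshold, (b) within `max_lookback` frames before it the trace
#' was at least `required_rise_pct` percent of its height-above-trendline
#' lower, and (c) within `max_lookahead` frames after it the trace falls by
#' at least `required_fall_pct` percent of that height (if the trace ends
#' before the fall criterion can be evaluated the event is kept with a
#' missing decay time). Peak parameters are read from the raw dF/F0, not
#' the detrended trace: `amplitude` is the maximum unsmoothed dF/F0
#' within half a smoothing window of the detected peak; the smoothed
#' trace drives detection and timing, and the trendline is used only
#' inside the rise/fall percentage criteria.
#'
#' @param dff a `DffTrace` from [compute_dff()] (or a plain numeric dF/F0
#'   vector, in which case the threshold is computed with `threshold_rule`).
#' @param frame_rate_hz acquisition rate, for converting frames to seconds.
#' @param required_rise_pct,required_fall_pct rise/fall criteria as a
#'   percentage of the peak's height above the trendline (defaults 20, 15).
#' @param max_lookback,max_lookahead criterion search windows in frames
#'   (defaults 30, 25).
#' @param sg_window,sg_order Savitzky-Golay window (odd) and order.
#' @param ema_alpha smoothing factor of the two-sided EMA trendline.
#' @param threshold_rule rule used when `dff` is a plain vector.
#' @return data frame of class `CalciumEvents`, one row per transient:
#'   `roi_id`, `peak_frame`, `onset_frame`, `decay_end_frame`, `amplitude`
#'   (smoothed dF/F0 above trendline at the peak), `rise_s`, `decay_s`,
#'   `duration_s`.
#' @export
detect_peaks <- function(dff, frame_rate_hz = 1,
                         required_rise_pct = 20, required_fall_pct = 15,
                         max_lookback = 30, max_lookahead = 25,
                         sg_window = 9, sg_order = 3, ema_alpha = 0.05,
                         threshold_rule = c("mean_plus_sd", "ten_sem")) {
  threshold_rule <- match.arg(threshold_rule)
  if (inherits(dff, "DffTrace")) {
    x <- dff$dff; thr <- dff$threshold; roi_id <- dff$roi_id
  } else {
    x <- as.numeric(dff); thr <- firing_threshold(x, threshold_rule)
    roi_id <- NA_integer_
  }
  n <- length(x)
  if (sg_window %% 2 == 0 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  if (sg_window > n || max_lookback >= n || max_lookahead >= n)
    stop("window parameters exceed trace length")
  sm <- signal::sgolayfilt(x, p = sg_order, n = sg_window)
  trend <- two_sided_ema(x, ema_alpha)

  empty <- data.frame(roi_id = integer(), peak_frame = integer(),
                      onset_frame = integer(), decay_end_frame = integer(),
                      amplitude = numeric(), rise_s = numeric(),
                      decay_s = numeric(), duration_s = numeric())
  class(empty) <- c("CalciumEvents", "data.frame")

  # local maxima: strictly greater than the previous point and at least as
  # large as the next (first frame of a plateau wins)
  i <- 2:(n - 1)
  cand <- i[sm[i] > sm[i - 1] & sm[i] >= sm[i + 1]]
  cand <- cand[sm[cand] > thr]
  if (length(cand) == 0) return(empty)

  rows <- lapply(cand, function(p) {
    h <- sm[p] - trend[p]
    if (h <= 0) return(NULL)
    # (b) rise criterion: last pre-peak frame at/below the rise level
    rise_level <- sm[p] - (required_rise_pct / 100) * h
    lb <- max(1L, p - max_lookback)
    pre <- lb:(p - 1L)
    if (p == 1L || !any(sm[pre] <= rise_level)) return(NULL)
    onset <- max(pre[sm[pre] <= rise_level])
    # (c) fall criterion
    fall_level <- sm[p] - (required_fall_pct / 100) * h
    la <- min(n, p + max_lookahead)
    post <- if (p < n) (p + 1L):la else integer()
    decay_end <- NA_integer_
    if (any(sm[post] <= fall_level)) {
      decay_end <- min(post[sm[post] <= fall_level])
    } else if (p + max_lookahead <= n) {
      return(NULL)                      # window fully observed, no fall
    }                                   # else: trace ended first, keep
    rise_s <- (p - onset) / frame_rate_hz
    decay_s <- if (is.na(decay_end)) NA_real_ else
      (decay_end - p) / frame_rate_hz
    half <- sg_window %/% 2
    amp <- max(x[max(1L, p - half):min(n, p + half)])
    data.frame(roi_id = roi_id, peak_frame = p, onset_frame = onset,
               decay_end_frame = decay_end, amplitude = amp,
               rise_s = rise_s, decay_s = decay_s,
               duration_s = rise_s + decay_s)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("CalciumEvents", "data.frame")
  out
}

#' Detect transients for a whole trace matrix
#'
#' Convenience wrapper: computes dF/F0 and runs [detect_peaks()] per ROI.
#'
#' @param traces frames x ROI matrix from [extract_traces()].
#' @param frame_rate_hz acquisition rate.
#' @param window_frames baseline window for [compute_dff()].
#' @param ... passed to [detect_peaks()].
#' @return list with `events` (row-bound `CalciumEvents`) and `dff`
#'   (named list of `DffTrace`s).
#' @export
detect_events_all <- function(traces, frame_rate_hz = 1,
                              window_frames = 60, ...) {
  ids <- colnames(traces)
  dffs <- stats::setNames(lapply(ids, function(id)
    compute_dff(traces[, id], window_frames = window_frames,
                roi_id = as.integer(id))), ids)
  ev <- do.call(rbind, lapply(dffs, detect_peaks,
                              frame_rate_hz = frame_rate_hz, ...))
  rownames(ev) <- NULL
  list(events = ev, dff = dffs)
}

#' Binary firing raster
#'
#' ROI x frame matrix with 1 on frames from each event's onset through its
#' decay end (peak + lookahead when the decay end is unobserved).
#'
#' @param events a `CalciumEvents` data frame.
#' @param roi_ids ids defining the row order.
#' @param n_frames number of frames (columns).
#' @return binary integer matrix with ROI ids as row names.
#' @export
build_raster <- function(events, roi_ids, n_frames) {
  r <- matrix(0L, length(roi_ids), n_frames,
              dimnames = list(roi_ids, NULL))
  for (k in seq_len(nrow(events))) {
    i <- as.character(events$roi_id[k])
    to <- events$decay_end_frame[k]
    if (is.na(to)) to <- n_frames
    r[i, events$onset_frame[k]:min(to, n_frames)] <- 1L
  }
  r
}

#' Count spontaneously active neurons per imaging block
#'
#' A neuron counts as active in a block iff at least one of its transients
#' peaks inside the block's frame range. Returns per-block counts and
#' their mean (the "average of images" convention for 5-min blocks).
#'
#' @param events a `CalciumEvents` data frame.
#' @param blocks named list of frame ranges `c(first, last)`; default two
#'   5-min blocks of a 600-frame, 1-Hz session.
#' @return list with `per_block` (named integer vector) and `mean_active`.
#' @export
count_active <- function(events,
                         blocks = list(Image1 = c(1, 300),
                                       Image2 = c(301, 600))) {
  per <- vapply(blocks, function(b)
    length(unique(events$roi_id[events$peak_frame >= b[1] &
                                  events$peak_frame <= b[2]])),
    integer(1))
  list(per_block = per, mean_active = mean(per))
}

#' High-potassium response heatmap
#'
#' Binary ROI x frame heatmap under the 10*SEM firing-threshold rule:
#' entries are 1 where dF/F0 >= threshold. A neuron responds to the
#' depolarising epoch iff any epoch frame is 1.
#'
#' @param dffs named list of `DffTrace`s (thresholds are recomputed under
#'   `rule`).
#' @param epoch frame range `c(first, last)` of the high-potassium epoch.
#' @param rule threshold rule (default `"ten_sem"`).
#' @return list with `heatmap` (binary ROI x frame matrix), `responds`
#'   (named logical), and `pct_responding`.
#' @export
high_k_response <- function(dffs, epoch, rule = "ten_sem") {
  ids <- names(dffs)
  nf <- length(dffs[[1]]$dff)
  hm <- matrix(0L, length(ids), nf, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    thr <- firing_threshold(dffs[[i]]$dff, rule)
    # a zero threshold means a trace with no variability at all: nothing
    # to call a response
    hm[i, ] <- as.integer(thr > 0 & dffs[[i]]$dff >= thr)
  }
  resp <- apply(hm[, epoch[1]:epoch[2], drop = FALSE], 1, function(z)
    any(z == 1L))
  list(heatmap = hm, responds = resp,
       pct_responding = 100 * mean(resp))
}
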