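#' Photobleaching correction
#'
#' Removes the slow monotone intensity decay caused by photobleaching.
#' The default (`exponential_fit`) fits a global monoexponential
#' `a * exp(-t/tau) + c` to the frame-mean time series and divides every
#' frame by the fitted curve normalised to its first value, which inverts
#' a multiplicative whole-field bleach. If the fit fails to converge the
#' function falls back to `simple_ratio` with a warning: each frame is
#' rescaled so its mean matches the first frame's mean.
#'
#' @param movie a [movie_stack()] with at least 10 frames.
#' @param method `"exponential_fit"` (default) or `"simple_ratio"`.
#' @return corrected `MovieStack`; intensities remain nonnegative and the
#'   frame-mean series of the output carries no residual monotone trend on
#'   monoexponentially bleached input.
#' @export
bleach_correct <- function(movie, method = c("exponential_fit",
                                             "simple_ratio")) {
  method <- match.arg(method)
  nf <- n_frames(movie)
  if (nf < 10) stop("bleach correction needs at least 10 frames")
  m <- frame_means(movie$data)
  t <- (seq_len(nf) - 1) / movie$frame_rate_hz
  scale <- NULL
  if (method == "exponential_fit") {
    scale <- tryCatch({
      if (stats::sd(m) < 1e-12 * mean(m)) stop("constant movie")
      fit <- minpack.lm::nlsLM(
        m ~ a * exp(-t / tau) + c0,
        start = list(a = max(m[1] - min(m), 1e-3), tau = max(t) / 2,
                     c0 = min(m)),
        lower = c(0, 1e-6, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      f <- stats::predict(fit)
      if (any(f <= 0)) stop("nonpositive fit")
      f / f[1]
    }, error = function(e) NULL)
    if (is.null(scale)) {
      # constant movies need no correction; otherwise fall back
      if (stats::sd(m) < 1e-12 * max(mean(m), 1)) {
        scale <- rep(1, nf)
      } else {
        warning("exponential bleach fit did not converge; ",
                "falling back to simple_ratio")
        method <- "simple_ratio"
      }
    }
  }
  if (method == "simple_ratio") scale <- m / m[1]
  out <- movie
  out$data <- sweep(movie$data, 3, scale, "/")
  out$data[out$data < 0] <- 0
  out
}

frame_means <- function(arr) {
  d <- dim(arr)
  colMeans(matrix(arr, d[1] * d[2], d[3]))
}

#' Rigid motion correction by phase correlation
#'
#' Estimates a per-frame rigid integer-pixel translation against a
#' reference image (the movie mean, or the first frame) via FFT phase
#' correlation, and shifts each frame back. A frame whose estimated shift
#' exceeds 25% of the frame size is flagged and left unshifted.
#'
#' @param movie a [movie_stack()].
#' @param reference `"mean"` (default) or `"first_frame"`.
#' @return list with `movie` (corrected `MovieStack`) and `shifts`, a data
#'   frame `(frame, dy_px, dx_px, applied)` of the estimated translations
#'   in pixels.
#' @export
motion_correct <- function(movie, reference = c("mean", "first_frame")) {
  reference <- match.arg(reference)
  nf <- n_frames(movie)
  ref <- if (reference == "mean") apply(movie$data, c(1, 2), mean)
         else movie$data[, , 1]
  Fr <- stats::fft(ref)
  nr <- nrow(ref); nc <- ncol(ref)
  lim <- 0.25 * min(nr, nc)
  shifts <- matrix(0L, nf, 2)
  applied <- rep(TRUE, nf)
  out <- movie
  fill <- stats::median(movie$data)
  for (t in seq_len(nf)) {
    s <- phase_corr_shift(Fr, movie$data[, , t])
    shifts[t, ] <- s
    if (any(abs(s) > lim)) {
      applied[t] <- FALSE
    } else if (any(s != 0L)) {
      out$data[, , t] <- shift_frame(movie$data[, , t], -s[1], -s[2],
                                     fill = fill)
    }
  }
  list(movie = out,
       shifts = data.frame(frame = seq_len(nf), dy_px = shifts[, 1],
                           dx_px = shifts[, 2], applied = applied))
}

# shift (dy, dx) such that frame == reference translated by (dy, dx)
phase_corr_shift <- function(Fref, frame) {
  Ff <- stats::fft(frame)
  cp <- Ff * Conj(Fref)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE))
  peak <- which.max(r)
  nr <- nrow(frame)
  dy <- (peak - 1) %% nr
  dx <- (peak - 1) %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > ncol(frame) / 2) dx <- dx - ncol(frame)
  c(as.integer(dy), as.integer(dx))
}

#' Flag low-quality frames
#'
#' Frames with large estimated motion or abrupt whole-field intensity
#' jumps are flagged (never deleted, so indices stay aligned with the 1 Hz
#' timestamps); downstream trace extraction interpolates across them.
#' Intensity jumps are measured against a running median of the frame
#' means, which is insensitive to slow bleaching.
#'
#' @param movie a [movie_stack()].
#' @param shifts optional shift table from [motion_correct()].
#' @param max_shift_px flag frames whose estimated |shift| exceeds this.
#' @param max_mean_jump_frac flag frames whose frame mean deviates from the
#'   local running median by more than this fraction.
#' @param median_window window (frames) of the running median (odd).
#' @return the movie with updated `kept` flags.
#' @export
drop_bad_frames <- function(movie, shifts = NULL, max_shift_px = 5,
                            max_mean_jump_frac = 0.2, median_window = 11) {
  stopifnot(max_shift_px > 0, max_mean_jump_frac > 0)
  nf <- n_frames(movie)
  m <- frame_means(movie$data)
  ref <- stats::runmed(m, k = min(median_window,
                                  if (nf %% 2) nf else nf - 1),
                       endrule = "median")
  bad <- abs(m - ref) / pmax(ref, 1e-12) > max_mean_jump_frac
  if (!is.null(shifts))
    bad <- bad | pmax(abs(shifts$dy_px), abs(shifts$dx_px)) > max_shift_px
  if (mean(bad) > 0.2)
    stop(sprintf("%.0f%% of frames flagged bad; movie unusable",
                 100 * mean(bad)))
  movie$kept <- movie$kept & !bad
  movie
}
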