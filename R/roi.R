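#' Detect active somata as ROIs
#'
#' Activity-based soma detection: the temporal standard-deviation image
#' (computed over kept frames) highlights pixels that fluoresce
#' transiently; it is Gaussian-smoothed, thresholded at a high percentile,
#' segmented by intensity watershed, filtered by equivalent-circle
#' diameter, and finally touching fragments whose traces correlate above
#' `merge_r` are merged back into single ROIs (the same 0.95 merge
#' threshold used by constrained-factorization toolboxes). Ground-truth or
#' manually curated ROI sets can always be supplied instead via
#' [roi_set_from_circles()].
#'
#' @param movie a preprocessed [movie_stack()].
#' @param min_diam_um,max_diam_um equivalent-diameter acceptance band (um).
#' @param activity_percentile percentile of the smoothed SD image above
#'   which pixels are considered active (default 98).
#' @param merge_r trace-correlation threshold for merging touching
#'   fragments (default 0.95).
#' @param smooth_sigma_px Gaussian sigma for SD-image smoothing.
#' @return a `RoiSet` (possibly empty, with a warning).
#' @export
detect_rois <- function(movie, min_diam_um = 10, max_diam_um = 40,
                        activity_percentile = 98, merge_r = 0.95,
                        smooth_sigma_px = 1.5) {
  d <- dim(movie$data)
  keep <- movie$kept
  m <- matrix(movie$data[, , keep], d[1] * d[2], sum(keep))
  sd_img <- matrix(row_sds(m), d[1], d[2])
  g <- as.matrix(EBImage::gblur(EBImage::Image(sd_img),
                                sigma = smooth_sigma_px))
  # the percentile sets how much of the field may be active; the robust
  # noise floor (median + 6 MAD of the smoothed SD image) keeps blank
  # noise movies from yielding spurious blobs
  thr <- max(stats::quantile(g, activity_percentile / 100),
             stats::median(g) + 6 * stats::mad(g))
  mask <- g > thr
  if (!any(mask)) {
    warning("no active pixels above the activity percentile; empty RoiSet")
    return(roi_set(matrix(0L, d[1], d[2]), movie$pixel_size_um, "auto"))
  }
  h <- (g - thr) * mask
  h <- h / max(h)
  ws <- EBImage::watershed(EBImage::Image(h), tolerance = 0.1)
  label <- matrix(as.integer(EBImage::imageData(ws)), d[1], d[2])
  label <- filter_by_diameter(label, movie$pixel_size_um,
                              min_diam_um, max_diam_um)
  if (!any(label > 0)) {
    warning("no ROIs within the diameter band; empty RoiSet")
    return(roi_set(label, movie$pixel_size_um, "auto"))
  }
  label <- merge_touching_correlated(label, movie, merge_r)
  rs <- roi_set(label, movie$pixel_size_um, "auto")
  if (nrow(rs$table) == 0) warning("zero ROIs detected")
  rs
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2) / (n - 1), 0))
}

filter_by_diameter <- function(label, px, min_diam_um, max_diam_um) {
  if (!any(label > 0)) return(label)
  areas <- tabulate(label)
  diam <- 2 * sqrt(areas / pi) * px
  bad <- which(diam < min_diam_um | diam > max_diam_um)
  label[label %in% bad] <- 0L
  relabel(label)
}

relabel <- function(label) {
  ids <- sort(setdiff(unique(as.vector(label)), 0L))
  if (length(ids) == 0) return(label)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  label[label > 0] <- map[label[label > 0]]
  label
}

# merge touching label pairs whose mean traces correlate above merge_r
merge_touching_correlated <- function(label, movie, merge_r) {
  repeat {
    ids <- sort(setdiff(unique(as.vector(label)), 0L))
    if (length(ids) < 2) return(label)
    rs <- roi_set(label, movie$pixel_size_um, "auto")
    tr <- extract_traces(movie, rs)
    adj <- touching_pairs(label, ids)
    merged <- FALSE
    for (k in seq_len(nrow(adj))) {
      a <- adj[k, 1]; b <- adj[k, 2]
      if (stats::sd(tr[, as.character(a)]) == 0 ||
          stats::sd(tr[, as.character(b)]) == 0) next
      if (stats::cor(tr[, as.character(a)], tr[, as.character(b)]) > merge_r) {
        label[label == b] <- a
        label <- relabel(label)
        merged <- TRUE
        break
      }
    }
    if (!merged) return(label)
  }
}

touching_pairs <- function(label, ids) {
  nr <- nrow(label); nc <- ncol(label)
  pairs <- rbind(
    cbind(as.vector(label[-nr, ]), as.vector(label[-1, ])),
    cbind(as.vector(label[, -nc]), as.vector(label[, -1])),
    cbind(as.vector(label[-nr, -nc]), as.vector(label[-1, -1])),
    cbind(as.vector(label[-nr, -1]), as.vector(label[-1, -nc])))
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0 & pairs[, 2] > 0,
                 , drop = FALSE]
  if (nrow(pairs) == 0) return(matrix(integer(), 0, 2))
  unique(t(apply(pairs, 1, sort)))
}

#' Extract per-ROI fluorescence traces
#'
#' `trace[t]` is the mean intensity over the ROI's mask pixels at frame t.
#' Frames flagged as dropped are linearly interpolated from neighbouring
#' kept frames (constant extrapolation at the ends).
#'
#' @param movie a [movie_stack()].
#' @param rois a `RoiSet` whose masks lie within the image bounds.
#' @return numeric matrix, frames x ROI, with ROI ids as column names.
#' @export
extract_traces <- function(movie, rois) {
  d <- dim(movie$data)
  if (any(dim(rois$label) != d[1:2]))
    stop("ROI label image does not match movie dimensions")
  ids <- rois$table$id
  m <- matrix(movie$data, d[1] * d[2], d[3])
  tr <- matrix(0, d[3], length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    pix <- which(rois$label == ids[j])
    if (length(pix) == 0) stop("ROI ", ids[j], " has an empty mask")
    tr[, j] <- if (length(pix) == 1) m[pix, ] else colMeans(m[pix, ,
                                                              drop = FALSE])
  }
  if (!all(movie$kept)) {
    t_all <- seq_len(d[3])
    for (j in seq_along(ids)) {
      tr[, j] <- stats::approx(t_all[movie$kept], tr[movie$kept, j],
                               xout = t_all, rule = 2)$y
    }
  }
  tr
}

#' Remove low-activity (false-positive) ROIs
#'
#' An automated surrogate for manual trace inspection: ROIs whose traces
#' show fewer than `min_events` detected transients or whose maximum dF/F0
#' never reaches `min_peak_dff` are removed.
#'
#' @param rois a `RoiSet`.
#' @param traces matrix from [extract_traces()].
#' @param frame_rate_hz acquisition rate used for peak detection.
#' @param min_events minimum number of detected transients (default 1).
#' @param min_peak_dff minimum peak dF/F0 (default 0.05).
#' @param ... further arguments passed to [detect_peaks()].
#' @return list with `rois` (the refined `RoiSet`) and `removed`, a data
#'   frame logging each removed ROI and the reason.
#' @export
refine_rois <- function(rois, traces, frame_rate_hz = 1, min_events = 1,
                        min_peak_dff = 0.05, ...) {
  ids <- rois$table$id
  keep <- logical(length(ids))
  reason <- character(length(ids))
  for (j in seq_along(ids)) {
    dff <- compute_dff(traces[, as.character(ids[j])])
    ev <- detect_peaks(dff, frame_rate_hz = frame_rate_hz, ...)
    n_ev <- nrow(ev)
    peak <- max(dff$dff)
    if (n_ev < min_events) reason[j] <- "low activity"
    else if (peak < min_peak_dff) reason[j] <- "low amplitude"
    keep[j] <- n_ev >= min_events && peak >= min_peak_dff
  }
  label <- rois$label
  label[label %in% ids[!keep]] <- 0L
  out <- roi_set(label, rois$pixel_size_um, rois$source)
  list(rois = out,
       removed = data.frame(id = ids[!keep], reason = reason[!keep]))
}

#' Count nuclei in a nuclear-label still image
#'
#' Standard particle-counting recipe: rolling-ball style background
#' subtraction (greyscale opening with a disk of `background_radius_px`,
#' computed on a downsampled copy for large radii), Otsu global
#' thresholding, distance-map watershed to split touching nuclei, and a
#' connected-component size filter.
#'
#' @param image 2-D numeric matrix.
#' @param background_radius_px rolling-ball radius in pixels (default 100).
#' @param min_area_px,max_area_px particle-size acceptance band (px).
#' @return list with `count` and `label` (integer label image).
#' @export
count_nuclei <- function(image, background_radius_px = 100,
                         min_area_px = 9, max_area_px = 2500) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (diff(rng) < 1e-9) {
    warning("empty or saturated image; count 0")
    return(list(count = 0L, label = matrix(0L, nrow(image), ncol(image))))
  }
  bg <- rolling_ball_background(image, background_radius_px)
  sub <- pmax(image - bg, 0)
  x <- (sub - min(sub)) / max(diff(range(sub)), 1e-12)
  thr <- EBImage::otsu(EBImage::Image(x))
  mask <- x > thr
  # degenerate-image guard: on a blank (noise-only) image Otsu still
  # splits; demand real foreground/background contrast before counting
  bg_sd <- stats::sd(x[!mask])
  if (!any(mask) || !is.finite(bg_sd) ||
      (mean(x[mask]) - mean(x[!mask])) < 5 * max(bg_sd, 1e-6)) {
    warning("no nuclei-like contrast in image; count 0")
    return(list(count = 0L, label = matrix(0L, nrow(image), ncol(image))))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1)
  label <- matrix(as.integer(EBImage::imageData(ws)), nrow(image))
  areas <- if (max(label) > 0) tabulate(label) else integer()
  bad <- which(areas < min_area_px | areas > max_area_px)
  label[label %in% bad] <- 0L
  label <- relabel(label)
  list(count = length(setdiff(unique(as.vector(label)), 0L)), label = label)
}

# greyscale opening with a disk; large radii via ImageJ-style downsampling
rolling_ball_background <- function(image, radius_px) {
  shrink <- max(1L, floor(radius_px / 16))
  img <- EBImage::Image(image)
  if (shrink > 1) {
    small <- EBImage::resize(img, w = ceiling(nrow(image) / shrink))
    r <- max(1, round(radius_px / shrink))
  } else {
    small <- img
    r <- radius_px
  }
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  bg <- EBImage::opening(small, brush)
  if (shrink > 1)
    bg <- EBImage::resize(bg, w = nrow(image), h = ncol(image))
  as.matrix(bg)
}
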