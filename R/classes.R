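#' Construct a MovieStack
#'
#' A `MovieStack` bundles a single-channel time-lapse movie with its
#' acquisition metadata. Pixels are stored as a numeric array indexed
#' `[row, col, frame]`; rows/cols use 0-based pixel-centre coordinates when
#' converted to micrometres.
#'
#' @param data numeric array `rows x cols x frames`, all values finite and
#'   nonnegative.
#' @param frame_rate_hz acquisition frequency in Hz (1 Hz for a standard
#'   10-min, 600-frame session).
#' @param pixel_size_um physical pixel size in micrometres.
#' @param kept logical vector, one flag per frame; frames flagged `FALSE`
#'   are excluded from trace statistics and linearly interpolated during
#'   trace extraction. Defaults to all `TRUE`.
#' @return an object of class `MovieStack`.
#' @export
movie_stack <- function(data, frame_rate_hz = 1, pixel_size_um = 1,
                        kept = NULL) {
  if (length(dim(data)) != 3L)
    stop("movie data must be a 3-D array (rows x cols x frames)")
  if (dim(data)[3] < 2L)
    stop("a movie needs at least 2 frames")
  if (!all(is.finite(data)))
    stop("movie intensities must all be finite")
  if (!isTRUE(pixel_size_um > 0) || !isTRUE(frame_rate_hz > 0))
    stop("frame_rate_hz and pixel_size_um must be positive")
  n <- dim(data)[3]
  if (is.null(kept)) kept <- rep(TRUE, n)
  stopifnot(length(kept) == n)
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, kept = as.logical(kept)),
            class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MovieStack: %d x %d px, %d frames @ %g Hz, %g um/px (%d kept)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um,
              sum(x$kept)))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[3]

#' Construct a RoiSet
#'
#' An ROI set pairs a 2-D integer label image (0 = background, k = pixels of
#' ROI k) with a per-ROI table. Masks are pairwise disjoint by construction
#' of the label image. Centroids are reported in micrometres with the origin
#' at the centre of the top-left pixel; `diameter_um` is the
#' equivalent-circle diameter `2*sqrt(area/pi)*pixel_size_um`.
#'
#' @param label integer matrix of ROI labels.
#' @param pixel_size_um pixel size in micrometres.
#' @param source one of `"auto"`, `"manual"`, `"ground_truth"`.
#' @return object of class `RoiSet` with elements `label`, `table`
#'   (`id`, `centroid_x_um`, `centroid_y_um`, `diameter_um`, `area_px`),
#'   `pixel_size_um` and `source`.
#' @export
roi_set <- function(label, pixel_size_um,
                    source = c("auto", "manual", "ground_truth")) {
  source <- match.arg(source)
  label <- matrix(as.integer(label), nrow = nrow(label))
  ids <- sort(setdiff(unique(as.vector(label)), 0L))
  tab <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(label == id, arr.ind = TRUE)
    data.frame(id = id,
               # x = column direction, y = row direction, 0-based centres
               centroid_x_um = mean(idx[, 2] - 1) * pixel_size_um,
               centroid_y_um = mean(idx[, 1] - 1) * pixel_size_um,
               diameter_um = 2 * sqrt(nrow(idx) / pi) * pixel_size_um,
               area_px = nrow(idx))
  }))
  if (is.null(tab))
    tab <- data.frame(id = integer(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), diameter_um = numeric(),
                      area_px = integer())
  structure(list(label = label, table = tab,
                 pixel_size_um = pixel_size_um, source = source),
            class = "RoiSet")
}

#' @export
print.RoiSet <- function(x, ...) {
  cat(sprintf("RoiSet (%s): %d ROIs, %g um/px\n", x$source,
              nrow(x$table), x$pixel_size_um))
  invisible(x)
}

#' Build a RoiSet from circular ROI descriptions
#'
#' Renders centroid/diameter rows (e.g. ground-truth neurons, or a manually
#' curated CSV) into a label image so that downstream trace extraction is
#' identical for detected and supplied ROIs. Later rows win where disks
#' would overlap.
#'
#' @param centroids_um two-column matrix or data frame of x/y centroids (um).
#' @param diameters_um per-ROI diameter (um).
#' @param dim_px image size `c(rows, cols)`.
#' @param pixel_size_um pixel size (um).
#' @param ids optional integer ids (default sequential).
#' @param source provenance tag for the resulting set.
#' @return a `RoiSet`.
#' @export
roi_set_from_circles <- function(centroids_um, diameters_um, dim_px,
                                 pixel_size_um, ids = NULL,
                                 source = "ground_truth") {
  centroids_um <- as.matrix(centroids_um)
  n <- nrow(centroids_um)
  if (is.null(ids)) ids <- seq_len(n)
  label <- matrix(0L, dim_px[1], dim_px[2])
  for (i in seq_len(n)) {
    cx <- centroids_um[i, 1] / pixel_size_um   # 0-based col
    cy <- centroids_um[i, 2] / pixel_size_um   # 0-based row
    r <- diameters_um[i] / 2 / pixel_size_um
    label[disk_pixels(cy, cx, r, dim_px)] <- as.integer(ids[i])
  }
  roi_set(label, pixel_size_um, source = source)
}

# linear indices of pixels within radius r of 0-based centre (row0, col0)
disk_pixels <- function(row0, col0, r, dim_px) {
  rr <- max(0L, floor(row0 - r)):min(dim_px[1] - 1, ceiling(row0 + r))
  cc <- max(0L, floor(col0 - r)):min(dim_px[2] - 1, ceiling(col0 + r))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row0)^2 + (g$col - col0)^2 <= r^2
  g <- g[keep, , drop = FALSE]
  (g$col) * dim_px[1] + g$row + 1L        # 1-based linear index
}
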