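#' Read a single-channel TIFF movie
#'
#' Reads a multi-page TIFF into a [movie_stack()]. Metadata (frame
#' interval, pixel size) is taken from a `<path>.meta.json` sidecar
#' (written by [write_movie()]) or, failing that, from an ImageJ-style
#' description tag; otherwise the `frame_rate_hz` / `pixel_size_um`
#' arguments are used with a warning. Multi-channel pages are rejected.
#'
#' @param path TIFF file path.
#' @param frame_rate_hz,pixel_size_um fallback metadata.
#' @param scale factor by which stored [0, 1] samples are multiplied back
#'   to intensity units (the inverse of [write_movie()]'s scaling).
#' @return a `MovieStack`.
#' @export
read_movie <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL,
                       scale = 65535) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (length(pages) == 0) stop("no frames in ", path)
  if (length(dim(pages[[1]])) != 2)
    stop("multi-channel TIFF not supported: ", path)
  meta <- parse_imagej_description(attr(pages[[1]], "description"))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$frame_rate_hz)) meta$frame_rate_hz <- sc$frame_rate_hz
    if (!is.null(sc$pixel_size_um)) meta$pixel_size_um <- sc$pixel_size_um
  }
  if (is.null(frame_rate_hz)) {
    if (!is.na(meta$frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
    else { warning("no frame-rate metadata; assuming 1 Hz")
           frame_rate_hz <- 1 }
  }
  if (is.null(pixel_size_um)) {
    if (!is.na(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    else { warning("no pixel-size metadata; assuming 1 um/px")
           pixel_size_um <- 1 }
  }
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    if (any(dim(pages[[t]]) != dim(pages[[1]])))
      stop("truncated or inconsistent TIFF at frame ", t)
    arr[, , t] <- pages[[t]] * scale
  }
  movie_stack(arr, frame_rate_hz, pixel_size_um)
}

parse_imagej_description <- function(desc) {
  out <- list(frame_rate_hz = NA_real_, pixel_size_um = NA_real_)
  if (is.null(desc) || !nzchar(desc)) return(out)
  get_num <- function(key) {
    m <- regmatches(desc, regexec(paste0(key, "=([0-9.eE+-]+)"), desc))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else NA_real_
  }
  fi <- get_num("finterval")
  if (!is.na(fi) && fi > 0) out$frame_rate_hz <- 1 / fi
  out$pixel_size_um <- get_num("pixel_size_um")
  out
}

#' Write a movie as a multi-page TIFF with a metadata sidecar
#'
#' Intensities are rounded and stored as 16-bit samples (values clamped
#' to `[0, scale]`), so integer-valued movies round-trip exactly through
#' [read_movie()]. Frame interval and pixel size are recorded in a
#' `<path>.meta.json` sidecar that [read_movie()] picks up.
#'
#' @param movie a `MovieStack`.
#' @param path output path.
#' @param scale full-scale intensity mapped to the 16-bit maximum.
#' @return invisibly, `path`.
#' @export
write_movie <- function(movie, path, scale = 65535) {
  pages <- lapply(seq_len(n_frames(movie)), function(t)
    pmin(pmax(round(movie$data[, , t]) / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_rate_hz = movie$frame_rate_hz,
         frame_interval_s = 1 / movie$frame_rate_hz,
         pixel_size_um = movie$pixel_size_um, unit = "um"),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a still image as TIFF
#' @param image numeric matrix.
#' @param path output path.
#' @param scale full-scale intensity.
#' @return invisibly, `path`.
#' @export
write_image <- function(image, path, scale = 65535) {
  tiff::writeTIFF(pmin(pmax(round(image) / scale, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Session manifest
#'
#' Describes how a session's frames divide into labelled imaging blocks
#' (e.g. three 5-min spontaneous blocks and one terminal high-potassium
#' block), with stage/animal/treatment annotations.
#'
#' @param blocks named list of frame ranges `c(first, last)`.
#' @param n_frames session length; ranges must lie within it and not
#'   overlap.
#' @param high_k_block name of the (at most one) high-potassium block,
#'   or `NA`.
#' @param stage,animal_id,treatment free-text annotations.
#' @return list of class `SessionManifest`.
#' @export
session_manifest <- function(blocks, n_frames,
                             high_k_block = NA_character_,
                             stage = NA_character_,
                             animal_id = NA_character_,
                             treatment = NA_character_) {
  stopifnot(is.list(blocks), length(blocks) >= 1,
            !is.null(names(blocks)))
  for (b in blocks)
    if (b[1] < 1 || b[2] > n_frames || b[1] > b[2])
      stop("block range outside the session")
  covered <- unlist(lapply(blocks, function(b) b[1]:b[2]))
  if (anyDuplicated(covered)) stop("block frame ranges overlap")
  if (!is.na(high_k_block) && !high_k_block %in% names(blocks))
    stop("high_k_block must name one of the blocks")
  structure(list(blocks = blocks, n_frames = n_frames,
                 high_k_block = high_k_block, stage = stage,
                 animal_id = animal_id, treatment = treatment),
            class = "SessionManifest")
}

#' Temporal color-coded activity map
#'
#' For one imaging block: F0 = mean image of the block; each frame's
#' F - F0 is Gaussian-smoothed, then every pixel is colored by the hue of
#' the frame at which its response peaks, with brightness scaled by the
#' response magnitude. A static block renders uniformly dark.
#'
#' @param movie a `MovieStack`.
#' @param block frame range `c(first, last)` (at least 2 frames).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @return an rows x cols x 3 RGB array in [0, 1].
#' @export
render_temporal_map <- function(movie, block, sigma = 1) {
  fr <- block[1]:block[2]
  if (length(fr) < 2) stop("block needs at least 2 frames")
  sub <- movie$data[, , fr, drop = FALSE]
  f0 <- apply(sub, c(1, 2), mean)
  d <- dim(sub)
  best_t <- matrix(1, d[1], d[2])
  best_v <- matrix(0, d[1], d[2])
  for (k in seq_along(fr)) {
    df <- as.matrix(EBImage::gblur(EBImage::Image(sub[, , k] - f0),
                                   sigma = sigma))
    upd <- df > best_v
    best_v[upd] <- df[upd]
    best_t[upd] <- k
  }
  vmax <- max(best_v)
  value <- if (vmax > 0) pmin(best_v / vmax, 1) else best_v
  hue <- 0.75 * (best_t - 1) / max(length(fr) - 1, 1)  # blue->red sweep
  col <- grDevices::hsv(h = as.vector(hue), s = 1, v = as.vector(value))
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, dim = c(d[1], d[2], 3))
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  out
}

#' Run the full analysis pipeline on one session
#'
#' Stages, in order: simulate (or read) the movie, preprocess (bleach,
#' motion, frame QC), detect or load ROIs, extract traces, detect events,
#' correlate, summarize the population, and render maps. Per-stage tables
#' are written as CSV/JSON under `out_dir` together with a run log and a
#' machine-readable `summary.json` carrying the seed and config hash, so
#' reruns with the same config are reproducible.
#'
#' @param config a list (or path to a YAML file) with optional entries:
#'   `seed`, `sim` (arguments to [sim_config()]), `movie_path` (read a
#'   TIFF instead of simulating), `rois` (`"auto"` or `"ground_truth"`),
#'   `blocks` (named list of frame ranges; default two 5-min blocks),
#'   `n_total_neurons` (denominator for percent-active; defaults to the
#'   simulated neuron count), `render` (logical).
#' @param out_dir output directory (created).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "sim", "movie_path", "rois", "blocks",
             "n_total_neurons", "render")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] %s\n",
                                        format(Sys.time(), "%H:%M:%S"),
                                        sprintf(...)),
                                file = logf, append = TRUE)
  seed <- config$seed %||% 1L
  stage <- "simulate"
  summary <- list(seed = seed, config_hash = rlang::hash(config))
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$movie_path)) {
      movie <- read_movie(config$movie_path)
    } else {
      cfg <- do.call(sim_config, c(config$sim %||% list(),
                                   if (is.null(config$sim$seed))
                                     list(seed = seed)))
      sim <- simulate_movie(cfg)
      movie <- sim$movie; truth <- sim$truth
      write_ground_truth(truth, file.path(out_dir, "ground_truth"))
    }
    log_line("simulate: %d frames", n_frames(movie))

    stage <- "preprocess"
    movie <- bleach_correct(movie)
    mc <- motion_correct(movie)
    movie <- drop_bad_frames(mc$movie, mc$shifts)
    utils::write.csv(mc$shifts, file.path(out_dir, "shifts.csv"),
                     row.names = FALSE)
    log_line("preprocess: %d/%d frames kept", sum(movie$kept),
             n_frames(movie))

    stage <- "roi"
    use_gt <- identical(config$rois, "ground_truth")
    if (use_gt) {
      if (is.null(truth)) stop("ground_truth ROIs need a simulated session")
      act <- truth$neurons[truth$neurons$active, ]
      rois <- roi_set_from_circles(
        act[, c("centroid_x_um", "centroid_y_um")], act$diameter_um,
        dim(movie$data)[1:2], movie$pixel_size_um, ids = act$id)
    } else {
      rois <- detect_rois(movie)
    }
    log_line("roi: %d ROIs (%s)", nrow(rois$table), rois$source)
    if (nrow(rois$table) < 2) stop("fewer than 2 ROIs; nothing to analyse")

    stage <- "traces"
    traces <- extract_traces(movie, rois)
    ref <- refine_rois(rois, traces, frame_rate_hz = movie$frame_rate_hz)
    rois <- ref$rois
    traces <- traces[, as.character(rois$table$id), drop = FALSE]
    utils::write.csv(cbind(frame = seq_len(nrow(traces)), traces),
                     file.path(out_dir, "traces.csv"), row.names = FALSE)
    utils::write.csv(rois$table, file.path(out_dir, "rois.csv"),
                     row.names = FALSE)

    stage <- "events"
    ed <- detect_events_all(traces, frame_rate_hz = movie$frame_rate_hz)
    utils::write.csv(ed$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    blocks <- config$blocks %||% list(Image1 = c(1, 300),
                                      Image2 = c(301, 600))
    act <- count_active(ed$events, blocks = blocks)
    raster <- build_raster(ed$events, rois$table$id, n_frames(movie))
    utils::write.csv(raster, file.path(out_dir, "raster.csv"),
                     row.names = TRUE)
    log_line("events: %d transients, mean active %.1f", nrow(ed$events),
             act$mean_active)

    stage <- "correlation"
    fraction_correlated <- NA_real_
    pairs <- NULL
    if (nrow(rois$table) >= 2) {
      sig <- vapply(ed$dff, thresholded_signal,
                    numeric(n_frames(movie)))
      pc <- pairwise_correlation(sig)
      keep <- rois$table$id %in% as.integer(colnames(pc$matrix))
      pairs <- pair_records(pc, roi_set_subset(rois, keep))
      cls <- classify_pairs(pairs)
      fraction_correlated <- cls$fraction_correlated_pct
      utils::write.csv(pairs, file.path(out_dir, "pair_records.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(unclass(pc$matrix)),
                       file.path(out_dir, "correlation_matrix.csv"))
    }

    stage <- "population"
    n_total <- config$n_total_neurons %||%
      (if (!is.null(truth)) nrow(truth$neurons) else NA_integer_)
    pct_active <- if (!is.na(n_total))
      percent_active(act$mean_active, n_total) else NA_real_
    comp <- subtype_composition(rois$table$diameter_um,
                                rep(TRUE, nrow(rois$table)))
    utils::write.csv(comp, file.path(out_dir, "subtype_composition.csv"),
                     row.names = FALSE)

    stage <- "render"
    if (isTRUE(config$render %||% TRUE)) {
      b1 <- blocks[[1]]
      map <- render_temporal_map(movie, b1)
      png::writePNG(map, file.path(out_dir, "temporal_map.png"))
    }

    summary$n_rois <- nrow(rois$table)
    summary$n_events <- nrow(ed$events)
    summary$active_per_block <- as.list(act$per_block)
    summary$mean_active <- act$mean_active
    summary$n_total_neurons <- n_total
    summary$pct_active <- pct_active
    summary$fraction_correlated_pct <- fraction_correlated
    summary
  }, error = function(e) {
    log_line("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}

roi_set_subset <- function(rois, keep) {
  label <- rois$label
  label[!label %in% rois$table$id[keep]] <- 0L
  out <- rois
  out$label <- label
  out$table <- rois$table[keep, , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
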