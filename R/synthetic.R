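#' Simulation configuration for synthetic explant movies
#'
#' Defines a ground-truthed synthetic session mimicking a 10-min, 1-Hz
#' ex vivo recording of a ganglion explant: a mosaic of circular GCaMP6s
#' somata drawn from a small/medium/large diameter mixture, sparse
#' Poisson-timed calcium transients in a configured fraction of neurons,
#' a minority of spatially proximal correlated pairs, monoexponential
#' photobleaching, additive Gaussian noise, optional rigid jitter and an
#' optional terminal high-potassium epoch of global activation.
#'
#' Defaults encode the neonatal (P4-P6) study conditions: a 660 x 660 um
#' imaging locus, 600 frames at 1 Hz, 12.3% of neurons active, and a
#' 67.3/27.3/5.4 SD/MD/LD soma mixture anchored on measured marker-positive
#' diameters (~18.1 um nociceptor-like, ~26.4 um mechanosensory-like).
#'
#' @param field_size_um side of the square imaging field (um).
#' @param pixels_per_side image side in pixels (3 um/px at the defaults).
#' @param frame_rate_hz acquisition rate (Hz).
#' @param n_frames number of frames in the session.
#' @param n_neurons number of somata to place.
#' @param diameter_mixture data frame with columns `mean_um`, `sd_um`,
#'   `weight` and rows named SD/MD/LD; weights must sum to 1.
#' @param event_rate_per_min Poisson transient rate per active neuron.
#' @param frac_active fraction of neurons with nonzero event rate.
#' @param n_correlated_pairs number of planted correlated neuron pairs.
#' @param correlated_pair_max_dist_um maximum centroid distance for a
#'   planted pair.
#' @param rise_tau_s,decay_tau_s transient kernel time constants (s);
#'   rise << decay for a GCaMP6s-like indicator.
#' @param event_amp_dff peak transient amplitude in dF/F0 units.
#' @param baseline_f resting soma fluorescence (arbitrary units).
#' @param background_f tissue background fluorescence.
#' @param bleach_tau_s monoexponential photobleaching time constant (s),
#'   or `NA` for no bleaching.
#' @param noise_sd additive Gaussian noise, expressed as a fraction of
#'   `baseline_f` (so `event_amp_dff / noise_sd` is the event SNR).
#' @param jitter_px standard deviation of the rigid per-frame jitter (px);
#'   0 disables motion.
#' @param high_k_start_frame first frame of a terminal high-potassium
#'   epoch in which every neuron is driven, or `NA` for none.
#' @param event_epoch two frames `c(first, last)` restricting spontaneous
#'   event onsets (used to emulate activity blockade); default the whole
#'   session.
#' @param seed master RNG seed; per-neuron event streams derive from it.
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(field_size_um = 660,
                       pixels_per_side = 220,
                       frame_rate_hz = 1,
                       n_frames = 600,
                       n_neurons = 300,
                       diameter_mixture = default_diameter_mixture(),
                       event_rate_per_min = 1,
                       frac_active = 0.123,
                       n_correlated_pairs = 10,
                       correlated_pair_max_dist_um = 150,
                       rise_tau_s = 1.5,
                       decay_tau_s = 4,
                       event_amp_dff = 0.5,
                       baseline_f = 100,
                       background_f = 20,
                       bleach_tau_s = 600,
                       noise_sd = 0.05,
                       jitter_px = 0,
                       high_k_start_frame = NA,
                       event_epoch = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$event_epoch)) cfg$event_epoch <- c(1L, n_frames)
  validate_sim_config(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

#' @rdname sim_config
#' @export
default_diameter_mixture <- function() {
  data.frame(class = c("SD", "MD", "LD"),
             mean_um = c(16.5, 22.5, 28),
             sd_um = c(2, 1.3, 1.8),
             weight = c(0.673, 0.273, 0.054))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$field_size_um > 0, cfg$pixels_per_side >= 8,
            cfg$frame_rate_hz > 0, cfg$n_frames >= 2, cfg$n_neurons >= 0,
            cfg$event_rate_per_min >= 0,
            cfg$frac_active >= 0, cfg$frac_active <= 1,
            cfg$n_correlated_pairs >= 0,
            cfg$correlated_pair_max_dist_um > 0,
            cfg$rise_tau_s > 0, cfg$decay_tau_s > 0,
            cfg$event_amp_dff >= 0, cfg$baseline_f > 0,
            cfg$noise_sd >= 0, cfg$jitter_px >= 0)
  if (abs(sum(cfg$diameter_mixture$weight) - 1) > 1e-6)
    stop("diameter mixture weights must sum to 1")
  if (!is.na(cfg$bleach_tau_s) && cfg$bleach_tau_s <= 0)
    stop("bleach_tau_s must be positive or NA")
  stopifnot(length(cfg$event_epoch) == 2,
            cfg$event_epoch[1] >= 1, cfg$event_epoch[2] <= cfg$n_frames)
  invisible(cfg)
}

# unit-peak difference-of-exponentials transient kernel sampled at dt
transient_kernel <- function(n, rise_tau_s, decay_tau_s, frame_rate_hz) {
  t <- (seq_len(n) - 1) / frame_rate_hz
  k <- (1 - exp(-t / rise_tau_s)) * exp(-t / decay_tau_s)
  # analytic peak of the continuous kernel, used to normalise to unit max
  tp <- rise_tau_s * log(1 + decay_tau_s / rise_tau_s)
  kp <- (1 - exp(-tp / rise_tau_s)) * exp(-tp / decay_tau_s)
  k / kp
}

# derive a 32-bit substream seed from the master seed
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1000003) %% 2147483647)
}

place_somata <- function(cfg, radii_px, margin_px = 1, max_tries = 2000) {
  n <- length(radii_px)
  cx <- cy <- numeric(n)
  side <- cfg$pixels_per_side
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, radii_px[i] + 1, side - radii_px[i] - 2)
      y <- runif(1, radii_px[i] + 1, side - radii_px[i] - 2)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
        ok <- all(d2 > (radii_px[j] + radii_px[i] + margin_px)^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) stop("soma placement failed: field too crowded for ",
                  n, " neurons")
  }
  cbind(col = cx, row = cy)
}

#' Simulate a ground-truthed calcium-imaging movie
#'
#' Renders `movie = background + somata * (1 + sum of transients)` with the
#' double-exponential kernel `(1 - exp(-t/rise)) * exp(-t/decay)` normalised
#' to unit peak, then applies global multiplicative photobleaching
#' `exp(-t/bleach_tau)`, rigid integer-pixel jitter and additive Gaussian
#' noise. Output is deterministic given `cfg$seed`.
#'
#' Planted correlated pairs are placed within
#' `correlated_pair_max_dist_um` of each other and share at least 80% of
#' their event onsets (shared onsets get independent jitter of at most one
#' frame), which yields Pearson r > 0.5 on thresholded dF/F0 at 1 Hz.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `movie` (a [movie_stack()]) and `truth`
#'   (class `GroundTruth`): `neurons` (id, centroid, diameter, size class,
#'   active flag), `events` (neuron_id, onset_frame), `pairs` (planted
#'   correlated pairs), `jitter` (per-frame planted shift), and the global
#'   bleach/noise constants.
#' @export
simulate_movie <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  side <- cfg$pixels_per_side
  px <- cfg$field_size_um / cfg$pixels_per_side
  nf <- cfg$n_frames
  n <- cfg$n_neurons

  mix <- cfg$diameter_mixture
  cls_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  diam_um <- pmax(6, rnorm(n, mix$mean_um[cls_idx], mix$sd_um[cls_idx]))
  radii_px <- diam_um / 2 / px

  # active set: correlated pairs are planted among the active neurons
  n_active <- round(cfg$frac_active * n)
  if (cfg$n_correlated_pairs * 2 > n_active && cfg$n_correlated_pairs > 0)
    stop("not enough active neurons to host the requested correlated pairs")
  active <- rep(FALSE, n)
  if (n_active > 0) active[sample.int(n, n_active)] <- TRUE

  centres <- place_somata(cfg, radii_px)

  # pull pair members spatially together: re-place the second member of
  # each planted pair near the first (rejection keeps masks disjoint)
  pairs <- NULL
  if (cfg$n_correlated_pairs > 0) {
    act_ids <- which(active)
    picked <- matrix(act_ids[seq_len(2 * cfg$n_correlated_pairs)],
                     ncol = 2, byrow = TRUE)
    maxd_px <- cfg$correlated_pair_max_dist_um / px
    for (k in seq_len(nrow(picked))) {
      a <- picked[k, 1]; b <- picked[k, 2]
      for (try in 1:2000) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, radii_px[a] + radii_px[b] + 2, max(maxd_px * 0.9, radii_px[a] + radii_px[b] + 3))
        x <- centres[a, "col"] + rad * cos(ang)
        y <- centres[a, "row"] + rad * sin(ang)
        if (x < radii_px[b] + 1 || x > side - radii_px[b] - 2 ||
            y < radii_px[b] + 1 || y > side - radii_px[b] - 2) next
        others <- setdiff(seq_len(n), b)
        d2 <- (centres[others, "col"] - x)^2 + (centres[others, "row"] - y)^2
        if (all(d2 > (radii_px[others] + radii_px[b] + 1)^2)) {
          centres[b, ] <- c(x, y); break
        }
        if (try == 2000) stop("soma placement failed for correlated pair")
      }
    }
    pairs <- data.frame(id_a = picked[, 1], id_b = picked[, 2])
  }

  # event onsets: Poisson-timed per active neuron from per-neuron substreams
  epoch <- cfg$event_epoch
  epoch_min <- (epoch[2] - epoch[1] + 1) / cfg$frame_rate_hz / 60
  events <- vector("list", n)
  for (i in which(active)) {
    set.seed(substream_seed(cfg$seed, i))
    k <- rpois(1, cfg$event_rate_per_min * epoch_min)
    if (k > 0)
      events[[i]] <- sort(sample(seq(epoch[1], epoch[2]), min(k, epoch[2] - epoch[1] + 1)))
  }
  # correlated pairs share >= 80% of onsets (jitter <= 1 frame)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$id_a[k]; b <- pairs$id_b[k]
      set.seed(substream_seed(cfg$seed, n + k))
      base <- events[[a]]
      if (length(base) == 0) {       # guarantee a pair has something to share
        base <- sort(sample(seq(epoch[1], epoch[2]),
                            max(1, round(cfg$event_rate_per_min * epoch_min))))
        events[[a]] <- base
      }
      shared <- base + sample(c(-1L, 0L, 1L), length(base),
                              replace = TRUE, prob = c(.15, .7, .15))
      shared <- unique(pmin(pmax(shared, epoch[1]), epoch[2]))
      # private events capped at 1/4 of the shared ones, so the partner
      # always shares >= 80% of its onsets with the pair lead
      n_own <- length(shared) %/% 4
      own <- if (n_own > 0) sample(seq(epoch[1], epoch[2]), n_own) else integer()
      events[[b]] <- sort(unique(c(shared, own)))
    }
  }

  # render: soma traces in dF/F units, then compose frame by frame
  kern <- transient_kernel(nf, cfg$rise_tau_s, cfg$decay_tau_s,
                           cfg$frame_rate_hz)
  dims <- c(side, side)
  pix_list <- lapply(seq_len(n), function(i)
    disk_pixels(centres[i, "row"], centres[i, "col"], radii_px[i], dims))

  base_img <- matrix(cfg$background_f, side, side)
  for (i in seq_len(n)) base_img[pix_list[[i]]] <- cfg$baseline_f

  set.seed(substream_seed(cfg$seed, 2L * n + 17L))
  hk <- cfg$high_k_start_frame
  mov <- array(0, dim = c(side, side, nf))
  traces <- matrix(0, nf, n)           # activity component, dF/F units
  for (i in seq_len(n)) {
    tr <- numeric(nf)
    for (t0 in events[[i]]) {
      seg <- t0:nf
      tr[seg] <- tr[seg] + cfg$event_amp_dff * kern[seq_along(seg)]
    }
    if (!is.na(hk)) {                  # sustained global depolarisation
      seg <- hk:nf
      tr[seg] <- tr[seg] + 3 * cfg$event_amp_dff *
        (1 - exp(-((seg - hk) / cfg$frame_rate_hz) / cfg$rise_tau_s))
    }
    traces[, i] <- tr
  }
  bleach <- if (is.na(cfg$bleach_tau_s)) rep(1, nf) else
    exp(-((seq_len(nf) - 1) / cfg$frame_rate_hz) / cfg$bleach_tau_s)

  jit <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  if (cfg$jitter_px > 0) {
    jit[, 1] <- as.integer(round(rnorm(nf, 0, cfg$jitter_px)))
    jit[, 2] <- as.integer(round(rnorm(nf, 0, cfg$jitter_px)))
    jit[1, ] <- 0L
  }

  for (t in seq_len(nf)) {
    fr <- base_img
    for (i in seq_len(n)) {
      a <- traces[t, i]
      if (a != 0) fr[pix_list[[i]]] <- cfg$baseline_f * (1 + a)
    }
    fr <- fr * bleach[t]
    if (any(jit[t, ] != 0L)) fr <- shift_frame(fr, jit[t, 1], jit[t, 2],
                                               fill = cfg$background_f * bleach[t])
    if (cfg$noise_sd > 0)
      fr <- fr + rnorm(length(fr), 0, cfg$noise_sd * cfg$baseline_f)
    mov[, , t] <- pmax(fr, 0)
  }

  truth <- structure(list(
    neurons = data.frame(id = seq_len(n),
                         centroid_x_um = centres[, "col"] * px,
                         centroid_y_um = centres[, "row"] * px,
                         diameter_um = diam_um,
                         size_class = mix$class[cls_idx],
                         active = active),
    events = if (any(lengths(events) > 0))
      data.frame(neuron_id = rep(seq_len(n), lengths(events)),
                 onset_frame = unlist(events))
      else data.frame(neuron_id = integer(), onset_frame = integer()),
    pairs = if (is.null(pairs)) data.frame(id_a = integer(), id_b = integer())
      else pairs,
    jitter = data.frame(frame = seq_len(nf), dy_px = jit[, 1],
                        dx_px = jit[, 2]),
    bleach_tau_s = cfg$bleach_tau_s, noise_sd = cfg$noise_sd,
    config = cfg), class = "GroundTruth")

  list(movie = movie_stack(mov, cfg$frame_rate_hz, px), truth = truth)
}

# rigid integer shift with constant fill (dy, dx in rows/cols)
shift_frame <- function(fr, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(fr), ncol(fr))
  nr <- nrow(fr); nc <- ncol(fr)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- fr[src_r[ok_r], src_c[ok_c]]
  out
}

#' Simulate a nuclear-label still image
#'
#' Renders `n_nuclei` bright disks of the given diameter on a dark
#' background with mild Gaussian noise, for exercising the nuclei-counting
#' procedure. Disks are placed with at least `min_gap_px` pixels between
#' their rims; `min_gap_px = 0` allows touching nuclei, which the counting
#' watershed must then split.
#'
#' @param n_nuclei number of nuclei.
#' @param field_size_um field side (um).
#' @param pixels_per_side image side (px).
#' @param diameter_um nuclear diameter (um).
#' @param noise_sd additive noise as a fraction of the disk intensity.
#' @param min_gap_px minimum rim-to-rim gap in pixels (default 2).
#' @param seed RNG seed.
#' @return list with `image` (matrix, arbitrary intensity units with disk
#'   level 200 over background 10) and `truth` (count, centroids in um,
#'   pixel size).
#' @export
simulate_nuclei_image <- function(n_nuclei, field_size_um = 660,
                                  pixels_per_side = 440, diameter_um = 10,
                                  noise_sd = 0.02, min_gap_px = 2,
                                  seed = 1) {
  stopifnot(n_nuclei >= 0, diameter_um > 0)
  set.seed(seed)
  px <- field_size_um / pixels_per_side
  r <- diameter_um / 2 / px
  img <- matrix(10, pixels_per_side, pixels_per_side)
  cx <- cy <- numeric(n_nuclei)
  if (n_nuclei > 0) {
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in 1:4000) {
        x <- runif(1, r + 1, pixels_per_side - r - 2)
        y <- runif(1, r + 1, pixels_per_side - r - 2)
        if (i == 1 ||
            all((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2 >
                (2 * r + min_gap_px)^2)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) stop("nuclei placement failed: field too crowded")
    }
    for (i in seq_len(n_nuclei))
      img[disk_pixels(cy[i], cx[i], r,
                      c(pixels_per_side, pixels_per_side))] <- 200
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd * 200)
  img <- pmax(img, 0)
  list(image = img,
       truth = list(count = n_nuclei,
                    centroid_x_um = cx * px, centroid_y_um = cy * px,
                    diameter_um = diameter_um, pixel_size_um = px))
}

#' Write / read simulation ground truth
#'
#' Neurons and events are written as CSV (one row per neuron, one row per
#' event), scalars and the planted pair list as a JSON sidecar. Round-trips
#' losslessly through [read_ground_truth()].
#'
#' @param gt a `GroundTruth` from [simulate_movie()].
#' @param path directory to write into (created if needed).
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, path) {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  pn <- file.path(path, "neurons.csv")
  pe <- file.path(path, "events.csv")
  pj <- file.path(path, "scalars.json")
  utils::write.csv(gt$neurons, pn, row.names = FALSE)
  utils::write.csv(gt$events, pe, row.names = FALSE)
  scal <- list(pairs = gt$pairs, jitter = gt$jitter,
               bleach_tau_s = gt$bleach_tau_s, noise_sd = gt$noise_sd)
  jsonlite::write_json(scal, pj, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(pn, pe, pj))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  neurons <- utils::read.csv(file.path(path, "neurons.csv"))
  events <- utils::read.csv(file.path(path, "events.csv"))
  scal <- jsonlite::read_json(file.path(path, "scalars.json"),
                              simplifyVector = TRUE)
  structure(list(neurons = neurons, events = events,
                 pairs = as.data.frame(scal$pairs),
                 jitter = as.data.frame(scal$jitter),
                 bleach_tau_s = scal$bleach_tau_s,
                 noise_sd = scal$noise_sd),
            class = "GroundTruth")
}
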