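make_dff <- function(dff_values) {
  # wrap a prebuilt dF/F0 vector in a DffTrace for thresholding tests
  d <- compute_dff(100 * (1 + dff_values))
  d$dff <- dff_values
  d$threshold <- firing_threshold(dff_values, "mean_plus_sd")
  d
}

test_that("thresholding keeps supra-threshold frames and zeroes the rest", {
  set.seed(2)
  v <- c(rep(0.01, 80), 0.6, 0.7, rep(0.01, 18)) + rnorm(100, 0, 1e-3)
  d <- make_dff(v)
  s <- thresholded_signal(d)
  expect_true(all(s[v < d$threshold] == 0))
  expect_equal(s[v >= d$threshold], v[v >= d$threshold])

  low <- make_dff(rnorm(100, 0, 1e-3))           # nothing crosses mean+sd
  expect_true(any(thresholded_signal(low) == 0))
  b <- thresholded_signal(d, binary = TRUE)
  expect_true(all(b %in% c(0, 1)))

  high <- d
  high$threshold <- -1                            # everything supra
  expect_equal(thresholded_signal(high), high$dff)
})

test_that("pairwise correlation reproduces exact limiting cases", {
  x <- sin(seq_len(50))
  m <- cbind(a = x, b = x, c = -x)
  pc <- pairwise_correlation(m)
  r <- pc$matrix
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(unclass(r))), rep(1, 3))
})

test_that("correlation matrix matches the covariance-formula oracle", {
  set.seed(10)
  m <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("r", 1:10)))
  pc <- pairwise_correlation(m)
  expect_lt(max(abs(unclass(pc$matrix) - oracle_cor_matrix(m))), 1e-12)
})

test_that("zero-variance signals are dropped or flagged, never NA", {
  m <- cbind(a = rnorm(30), b = rep(2, 30), c = rnorm(30))
  pc <- pairwise_correlation(m)
  expect_equal(pc$dropped, "b")
  expect_false("b" %in% colnames(pc$matrix))

  pc2 <- pairwise_correlation(m, drop_zero_variance = FALSE)
  expect_true(all(is.finite(unclass(pc2$matrix))))
  flagged <- pc2$pairs[pc2$pairs$zero_variance, ]
  expect_true(all(flagged$pearson_r == 0))
})

test_that("pair distances follow the Euclidean formula", {
  tab <- data.frame(id = 1:3, centroid_x_um = c(0, 3, 0),
                    centroid_y_um = c(0, 4, 0))
  d <- pair_distances(tab)
  expect_equal(d$distance_um[d$roi_i == 1 & d$roi_j == 2], 5)
  expect_equal(d$distance_um[d$roi_i == 1 & d$roi_j == 3], 0)

  set.seed(20)
  tab2 <- data.frame(id = 1:12, centroid_x_um = runif(12, 0, 600),
                     centroid_y_um = runif(12, 0, 600))
  got <- pair_distances(tab2)
  want <- oracle_distances(tab2$centroid_x_um, tab2$centroid_y_um)
  expect_equal(sort(got$distance_um), sort(want), tolerance = 1e-12)
  d57 <- got$distance_um[got$roi_i == 5 & got$roi_j == 7]
  expect_equal(d57, sqrt(diff(tab2$centroid_x_um[c(5, 7)])^2 +
                           diff(tab2$centroid_y_um[c(5, 7)])^2),
               tolerance = 1e-12)
})

test_that("pairs split at r > 0.5 with the printed-counts fraction", {
  rec <- data.frame(pearson_r = c(rep(0.8, 129), rep(0.1, 6547)))
  cls <- classify_pairs(rec)
  expect_equal(cls$n_correlated, 129)
  expect_equal(cls$n_non_correlated, 6547)
  expect_equal(round(cls$fraction_correlated_pct, 1), 1.9)

  expect_equal(classify_pairs(data.frame(pearson_r = rep(0, 10)))$
                 fraction_correlated_pct, 0)
  # r = 0.5 exactly is non-correlated (strict inequality)
  expect_equal(classify_pairs(data.frame(pearson_r = 0.5))$n_correlated, 0)
  expect_error(classify_pairs(data.frame(pearson_r = numeric())), "no pair")
})

test_that("the correlated fraction is invariant to pair order", {
  set.seed(30)
  rec <- data.frame(pearson_r = runif(200, -1, 1))
  f1 <- classify_pairs(rec)$fraction_correlated_pct
  f2 <- classify_pairs(rec[sample.int(200), , drop = FALSE])$
    fraction_correlated_pct
  expect_equal(f1, f2)
})

test_that("Mann-Whitney matches exact enumeration and base R", {
  # spec fixture: complete separation of two triples
  mw <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(mw$U, 9)          # all 9 pairs favour x
  expect_equal(mw$p_value, 0.1)  # smallest attainable two-sided p
  mw2 <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw2$U, 0)
  expect_equal(mw2$p_value, 0.1)

  # identical samples: p about 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  # random tie-free small samples agree with the base-R exact test
  set.seed(40)
  for (rep in 1:20) {
    x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:5, 1))
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  # large samples agree with the base-R normal approximation
  set.seed(41)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  mine <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("distance comparison reports medians and a sane p", {
  same <- compare_distance_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  sep <- compare_distance_distributions(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$median_correlated, 2)
  expect_equal(sep$median_non_correlated, 11)
  expect_error(compare_distance_distributions(numeric(), 1:3), "nonempty")
})

test_that("planted proximal correlated pairs are recovered", {
  cfg <- small_cfg(field_size_um = 500, pixels_per_side = 150,
                   n_neurons = 40, frac_active = 0.6,
                   n_correlated_pairs = 4, correlated_pair_max_dist_um = 100,
                   n_frames = 300, event_rate_per_min = 1, noise_sd = 0.05,
                   seed = 33)
  sim <- simulate_movie(cfg)
  nrn <- sim$truth$neurons
  act <- nrn[nrn$active, ]
  rois <- roi_set_from_circles(act[, c("centroid_x_um", "centroid_y_um")],
                               act$diameter_um, c(150, 150),
                               sim$movie$pixel_size_um, ids = act$id)
  ed <- detect_events_all(extract_traces(sim$movie, rois))
  sig <- vapply(ed$dff, thresholded_signal, numeric(300))
  pc <- pairwise_correlation(sig)
  rec <- pair_records(pc, rois)
  planted_key <- paste(pmin(sim$truth$pairs$id_a, sim$truth$pairs$id_b),
                       pmax(sim$truth$pairs$id_a, sim$truth$pairs$id_b))
  rec_key <- paste(pmin(as.integer(rec$roi_i), as.integer(rec$roi_j)),
                   pmax(as.integer(rec$roi_i), as.integer(rec$roi_j)))
  planted_r <- rec$pearson_r[rec_key %in% planted_key]
  expect_gte(mean(planted_r > 0.5), 0.8)
  cls <- classify_pairs(rec)
  cmp <- compare_distance_distributions(cls$correlated$distance_um,
                                        cls$non_correlated$distance_um)
  expect_lt(cmp$median_correlated, cmp$median_non_correlated)
})

test_that("clustering orders perfect blocks contiguously", {
  ids <- paste0("r", 1:6)
  cm <- diag(6) * 0.0
  cm[1:3, 1:3] <- 0.9; cm[4:6, 4:6] <- 0.9
  diag(cm) <- 1
  dimnames(cm) <- list(ids, ids)
  class(cm) <- c("CorrelationMatrix", class(cm))
  cl <- cluster_matrix(cm)
  pos <- match(ids, cl$order)
  expect_true(max(pos[1:3]) <= 3 || min(pos[1:3]) >= 4)  # block 1 contiguous

  # near-identity matrix: no merge below distance 0.5
  cm2 <- diag(6); dimnames(cm2) <- list(ids, ids)
  cm2[upper.tri(cm2)] <- 0.05; cm2[lower.tri(cm2)] <- 0.05; diag(cm2) <- 1
  class(cm2) <- c("CorrelationMatrix", class(cm2))
  expect_true(all(cluster_matrix(cm2)$hclust$height > 0.5))

  # merge heights are monotone nondecreasing for average linkage
  set.seed(50)
  z <- matrix(rnorm(200), 20)
  cmr <- cor(z)
  dimnames(cmr) <- list(paste0("k", 1:10), paste0("k", 1:10))
  class(cmr) <- c("CorrelationMatrix", class(cmr))
  h <- cluster_matrix(cmr)$hclust$height
  expect_true(all(diff(h) >= -1e-12))
})
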