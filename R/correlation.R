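#' Supra-threshold signal for correlation analysis
#'
#' Only transients exceeding the firing threshold enter the correlation
#' analysis: frames with dF/F0 below the trace's threshold are set to 0
#' and supra-threshold frames keep their dF/F0 value, preserving amplitude
#' information. (Binarization instead of zeroing is available via
#' `binary = TRUE`.)
#'
#' @param dff a `DffTrace`.
#' @param binary if `TRUE`, return a 0/1 trace instead.
#' @return numeric trace of the same length.
#' @export
thresholded_signal <- function(dff, binary = FALSE) {
  stopifnot(inherits(dff, "DffTrace"))
  out <- ifelse(dff$dff >= dff$threshold, dff$dff, 0)
  if (binary) out <- as.numeric(out > 0)
  out
}

#' All-pairs Pearson correlation of ROI signals
#'
#' Computes the Pearson correlation coefficient for every unordered ROI
#' pair. Zero-variance signals (never-firing ROIs) get r recorded as 0
#' with a flag, and can be excluded entirely with
#' `drop_zero_variance = TRUE` (the default when building pair records:
#' ROI sets are placed on spontaneously firing neurons).
#'
#' @param signals frames x ROI numeric matrix (column names = ROI ids).
#' @param drop_zero_variance drop constant signals before pairing.
#' @return list with `matrix` (symmetric, unit diagonal, class
#'   `CorrelationMatrix`), `pairs` (data frame `roi_i`, `roi_j`,
#'   `pearson_r`, `zero_variance`), and `dropped` (ids of constant
#'   signals, if dropped).
#' @export
pairwise_correlation <- function(signals, drop_zero_variance = TRUE) {
  if (ncol(signals) < 2) stop("need at least 2 ROIs")
  ids <- colnames(signals)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(signals)))
  sds <- apply(signals, 2, stats::sd)
  dropped <- character()
  if (drop_zero_variance && any(sds == 0)) {
    dropped <- ids[sds == 0]
    signals <- signals[, sds > 0, drop = FALSE]
    ids <- ids[sds > 0]
    sds <- sds[sds > 0]
    if (ncol(signals) < 2) stop("fewer than 2 nonconstant signals")
  }
  n <- ncol(signals)
  cm <- matrix(0, n, n, dimnames = list(ids, ids))
  ok <- sds > 0
  if (any(ok)) cm[ok, ok] <- stats::cor(signals[, ok, drop = FALSE])
  diag(cm) <- 1
  class(cm) <- c("CorrelationMatrix", class(cm))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(roi_i = ids[idx[, 1]], roi_j = ids[idx[, 2]],
                      pearson_r = cm[idx],
                      zero_variance = !ok[idx[, 1]] | !ok[idx[, 2]])
  list(matrix = cm, pairs = pairs, dropped = dropped)
}

#' Euclidean inter-ROI distances
#'
#' Distance between two ROIs = sqrt((x2 - x1)^2 + (y2 - y1)^2) on the
#' micrometre centroids, for every unordered pair.
#'
#' @param rois a `RoiSet` (or a data frame with `id`, `centroid_x_um`,
#'   `centroid_y_um`).
#' @return data frame `roi_i`, `roi_j`, `distance_um`.
#' @export
pair_distances <- function(rois) {
  tab <- if (inherits(rois, "RoiSet")) rois$table else rois
  n <- nrow(tab)
  if (n < 2) stop("need at least 2 ROIs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- tab$centroid_x_um[idx[, 2]] - tab$centroid_x_um[idx[, 1]]
  dy <- tab$centroid_y_um[idx[, 2]] - tab$centroid_y_um[idx[, 1]]
  data.frame(roi_i = as.character(tab$id[idx[, 1]]),
             roi_j = as.character(tab$id[idx[, 2]]),
             distance_um = sqrt(dx^2 + dy^2))
}

#' Build pair records (correlation + distance)
#'
#' Joins the all-pairs correlations with the inter-ROI distances into one
#' record per unordered pair, with the correlated flag at r > 0.5
#' (strictly: r = 0.5 is non-correlated).
#'
#' @param corr output of [pairwise_correlation()].
#' @param rois the matching `RoiSet`.
#' @param r_threshold correlation cutoff (default 0.5, strict).
#' @return data frame `roi_i`, `roi_j`, `pearson_r`, `distance_um`,
#'   `correlated`.
#' @export
pair_records <- function(corr, rois, r_threshold = 0.5) {
  d <- pair_distances(rois)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(corr$pairs$roi_i, corr$pairs$roi_j),
             key(d$roi_i, d$roi_j))
  out <- corr$pairs
  out$distance_um <- d$distance_um[m]
  out$correlated <- out$pearson_r > r_threshold
  out$zero_variance <- NULL
  out
}

#' Split pairs into correlated and non-correlated sets
#'
#' @param records pair records with a `pearson_r` column (and optionally a
#'   precomputed `correlated` flag, which is recomputed here).
#' @param r_threshold cutoff (default 0.5); pairs with r strictly greater
#'   are correlated.
#' @return list with `correlated`, `non_correlated` (data frames),
#'   `n_correlated`, `n_non_correlated`, and `fraction_correlated_pct`
#'   = 100 * correlated / total.
#' @export
classify_pairs <- function(records, r_threshold = 0.5) {
  if (nrow(records) == 0) stop("no pair records")
  corr <- records$pearson_r > r_threshold
  list(correlated = records[corr, , drop = FALSE],
       non_correlated = records[!corr, , drop = FALSE],
       n_correlated = sum(corr),
       n_non_correlated = sum(!corr),
       fraction_correlated_pct = 100 * sum(corr) / length(corr))
}

#' Compare distance distributions of correlated vs non-correlated pairs
#'
#' Two-sided Mann-Whitney U test on the inter-ROI distances of the two
#' groups, with group medians. Small samples (both groups <= 8, no ties)
#' use exact enumeration; otherwise the normal approximation with tie
#' correction.
#'
#' @param correlated_dist,non_correlated_dist numeric distance vectors.
#' @return list with `median_correlated`, `median_non_correlated`,
#'   `U`, `p_value`, `method`.
#' @export
compare_distance_distributions <- function(correlated_dist,
                                           non_correlated_dist) {
  if (length(correlated_dist) < 1 || length(non_correlated_dist) < 1)
    stop("both groups must be nonempty")
  mw <- mann_whitney_u(correlated_dist, non_correlated_dist)
  c(list(median_correlated = stats::median(correlated_dist),
         median_non_correlated = stats::median(non_correlated_dist)),
    mw)
}

#' Two-sided Mann-Whitney U test
#'
#' Reports the U statistic of the first sample (number of (x, y) pairs
#' with x > y, counting ties as 1/2). For small samples (both n, m <= 8
#' and no ties across the pooled data) the two-sided p-value is computed
#' by complete enumeration of all choose(n+m, n) group assignments;
#' otherwise by the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max maximum group size for the exact path (default 8).
#' @return list `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (n <= exact_max && m <= exact_max && !ties) {
    # enumerate every assignment of n ranks out of n+m
    combos <- utils::combn(n + m, n)
    Us <- colSums(matrix(sort(rk)[combos], nrow = n)) - n * (n + 1) / 2
    mu <- n * m / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact enumeration"))
  }
  N <- n + m
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  mu <- n * m / 2
  if (sigma2 <= 0)
    return(list(U = U, p_value = 1, method = "degenerate (all tied)"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-z)),
       method = "normal approximation with tie correction")
}

#' Hierarchically cluster a correlation matrix
#'
#' Agglomerative clustering on the distance 1 - r, returning the leaf
#' order for plotting a reordered matrix.
#'
#' @param cm a `CorrelationMatrix`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return list with `order` (ids in dendrogram order), `hclust` (the
#'   stats::hclust object) and `reordered` (the permuted matrix).
#' @export
cluster_matrix <- function(cm, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(isSymmetric(unclass(cm)))
  hc <- stats::hclust(stats::as.dist(1 - unclass(cm)), method = linkage)
  ord <- rownames(cm)[hc$order]
  list(order = ord, hclust = hc,
       reordered = unclass(cm)[hc$order, hc$order])
}
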