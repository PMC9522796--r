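#' Classify a soma diameter into SD / MD / LD
#'
#' Small-diameter (SD) neurons are < 20 um, medium-diameter (MD) 20-25 um
#' (closed interval: both boundaries are MD), large-diameter (LD) > 25 um.
#' SD is characteristic of nociceptors and MD-LD of mechanosensory
#' neurons.
#'
#' @param diameter_um positive diameter(s) in micrometres (vectorized).
#' @return factor with levels `SD`, `MD`, `LD`.
#' @export
classify_soma <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("diameters must be positive")
  cls <- ifelse(diameter_um < 20, "SD",
                ifelse(diameter_um <= 25, "MD", "LD"))
  factor(cls, levels = c("SD", "MD", "LD"))
}

#' Soma-size composition of all vs active neurons
#'
#' Percentage of SD/MD/LD neurons among all neurons and among the
#' spontaneously firing subset, reported at 1-decimal precision (raw
#' values are also returned).
#'
#' @param diameters_um per-neuron diameters.
#' @param active_flags logical, which neurons fired spontaneously.
#' @return data frame with `class`, `n_all`, `share_all_pct`, `n_active`,
#'   `share_active_pct` (rounded to 1 decimal) plus unrounded `_raw`
#'   columns.
#' @export
subtype_composition <- function(diameters_um, active_flags) {
  stopifnot(length(diameters_um) >= 1,
            length(active_flags) == length(diameters_um))
  cls <- classify_soma(diameters_um)
  n_all <- table(cls)
  n_act <- table(cls[active_flags])
  share_all <- 100 * as.numeric(n_all) / sum(n_all)
  share_act <- if (sum(n_act) > 0) 100 * as.numeric(n_act) / sum(n_act)
               else rep(NA_real_, 3)
  data.frame(class = levels(cls),
             n_all = as.integer(n_all),
             share_all_pct = round(share_all, 1),
             share_all_pct_raw = share_all,
             n_active = as.integer(n_act),
             share_active_pct = round(share_act, 1),
             share_active_pct_raw = share_act)
}

#' Estimate the active fraction within a soma-size subtype
#'
#' If `overall_active_pct` percent of all neurons fire spontaneously, and
#' a subtype makes up `share_active_pct` percent of the firing neurons but
#' `share_all_pct` percent of all neurons, then the percentage of that
#' subtype's neurons that fire is
#' `overall_active_pct * share_active_pct / share_all_pct`.
#'
#' @param overall_active_pct percentage of all neurons active (e.g. 12.3).
#' @param share_active_pct subtype share among active neurons (%).
#' @param share_all_pct subtype share among all neurons (%); must be > 0.
#' @return the estimated active percentage of the subtype (unrounded; the
#'   reporting layer rounds to the nearest integer).
#' @export
estimate_subtype_activity <- function(overall_active_pct, share_active_pct,
                                      share_all_pct) {
  if (any(share_all_pct <= 0))
    stop("share_all_pct must be positive")
  overall_active_pct * share_active_pct / share_all_pct
}

#' Percent of neurons firing spontaneously
#'
#' @param n_active number of spontaneously firing neurons (per 5-min
#'   block, averaged across blocks upstream).
#' @param n_total total number of neurons visible in the imaging locus
#'   (nuclei count); must be positive.
#' @return 100 * n_active / n_total.
#' @export
percent_active <- function(n_active, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  100 * n_active / n_total
}

#' Significance stars
#'
#' Convention: * p < 0.05, ** p < 0.005, *** p < 0.001, **** p < 0.0001;
#' "ns" otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 5e-3, "**",
                       ifelse(p < 5e-2, "*", "ns"))))
}

#' Compare a firing metric across groups
#'
#' Runs the chosen design on named group samples: one-way ANOVA with
#' Tukey's multiple comparisons, Kruskal-Wallis, two-sided Mann-Whitney,
#' or a paired two-tailed t test. A Shapiro-Wilk normality check per group
#' is reported as a diagnostic but never switches the design.
#'
#' @param samples named list of numeric vectors (exactly 2 groups for
#'   `mann_whitney` / `paired_t`).
#' @param design one of `"anova_tukey"`, `"kruskal_wallis"`,
#'   `"mann_whitney"`, `"paired_t"`.
#' @return list with `design`, `statistic`, `p_value`, `stars`,
#'   `pairwise` (Tukey table, for ANOVA), and `shapiro` (per-group
#'   normality p-values where computable).
#' @export
compare_groups <- function(samples, design = c("anova_tukey",
                                               "kruskal_wallis",
                                               "mann_whitney",
                                               "paired_t")) {
  design <- match.arg(design)
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  shapiro <- vapply(samples, function(s) {
    if (length(s) >= 3 && length(s) <= 5000 && stats::sd(s) > 0)
      stats::shapiro.test(s)$p.value else NA_real_
  }, numeric(1))
  df <- data.frame(value = unlist(samples, use.names = FALSE),
                   group = factor(rep(names(samples), lengths(samples)),
                                  levels = names(samples)))
  out <- list(design = design, shapiro = shapiro, pairwise = NULL)
  degenerate <- stats::sd(df$value) == 0
  if (design == "anova_tukey") {
    if (degenerate) {
      out$statistic <- NA_real_; out$p_value <- 1
      out$note <- "degenerate: zero variance"
    } else {
      fit <- stats::aov(value ~ group, data = df)
      an <- summary(fit)[[1]]
      out$statistic <- an[["F value"]][1]
      out$p_value <- an[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$group
      out$pairwise <- data.frame(comparison = rownames(tk),
                                 diff = tk[, "diff"],
                                 p_adj = tk[, "p adj"],
                                 stars = significance_stars(tk[, "p adj"]),
                                 row.names = NULL)
    }
  } else if (design == "kruskal_wallis") {
    if (degenerate) {
      out$statistic <- NA_real_; out$p_value <- 1
      out$note <- "degenerate: zero variance"
    } else {
      kt <- stats::kruskal.test(value ~ group, data = df)
      out$statistic <- unname(kt$statistic)
      out$p_value <- kt$p.value
    }
  } else if (design == "mann_whitney") {
    stopifnot(length(samples) == 2)
    mw <- mann_whitney_u(samples[[1]], samples[[2]])
    out$statistic <- mw$U
    out$p_value <- mw$p_value
    out$method <- mw$method
  } else {
    stopifnot(length(samples) == 2,
              length(samples[[1]]) == length(samples[[2]]),
              length(samples[[1]]) >= 2)
    d <- samples[[1]] - samples[[2]]
    if (stats::sd(d) == 0) {
      out$statistic <- NA_real_
      out$p_value <- if (all(d == 0)) 1 else 0
      out$note <- "degenerate: constant paired differences"
    } else {
      tt <- stats::t.test(samples[[1]], samples[[2]], paired = TRUE)
      out$statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    }
  }
  out$stars <- significance_stars(out$p_value)
  out
}

#' Before/after comparison of active-neuron counts
#'
#' For a session with a pre-drug and a post-drug imaging block: counts the
#' spontaneously active neurons in each block ([count_active()] with one
#' block each), their paired difference, and (optionally) temporal
#' color-coded maps of the two blocks.
#'
#' @param events a `CalciumEvents` data frame for the whole session.
#' @param pre_block,post_block frame ranges `c(first, last)`.
#' @param movie optional [movie_stack()]; when supplied, temporal maps of
#'   both blocks are rendered and returned.
#' @return list with `pre_active`, `post_active`, `difference`
#'   (pre - post), and optionally `map_pre`, `map_post` (RGB arrays).
#' @export
before_after_summary <- function(events, pre_block, post_block,
                                 movie = NULL) {
  if (missing(pre_block) || missing(post_block) ||
      is.null(pre_block) || is.null(post_block))
    stop("both pre and post blocks are required")
  counts <- count_active(events, blocks = list(pre = pre_block,
                                               post = post_block))
  out <- list(pre_active = unname(counts$per_block["pre"]),
              post_active = unname(counts$per_block["post"]),
              difference = unname(counts$per_block["pre"] -
                                    counts$per_block["post"]))
  if (!is.null(movie)) {
    out$map_pre <- render_temporal_map(movie, pre_block)
    out$map_post <- render_temporal_map(movie, post_block)
  }
  out
}
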