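# small, fast simulation configs shared across test files
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(field_size_um = 250, pixels_per_side = 100,
                   n_frames = 150, n_neurons = 15, frac_active = 0.6,
                   n_correlated_pairs = 0, noise_sd = 0.02, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# match detected ROI centroids to ground-truth active neurons; returns the
# ground-truth id per detected ROI (NA = false positive)
match_rois_to_truth <- function(rois, truth_neurons, slack_um = 3) {
  tab <- rois$table
  vapply(seq_len(nrow(tab)), function(i) {
    d <- sqrt((truth_neurons$centroid_x_um - tab$centroid_x_um[i])^2 +
                (truth_neurons$centroid_y_um - tab$centroid_y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= truth_neurons$diameter_um[j] / 2 + slack_um)
      truth_neurons$id[j] else NA_integer_
  }, integer(1))
}
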