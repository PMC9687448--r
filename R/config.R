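# Flat declarative run configuration (YAML). Every tunable of the pipeline
# appears with its default; stage blocks mirror the pipeline stages.

#' Default run configuration
#'
#' @param seed global seed.
#' @return nested list with `phantom`, `preprocess`, `augment`, `segment`,
#'   `classify`, `evaluate`, `track` blocks and the global `seed`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(preset = "desk", n_frames = 40L, radial_px_um = 5.0,
                   frame_pitch_mm = 0.2, catheter_radius_px = 12L,
                   lumen_radius_px = 50L, attenuation_mu = 0.012,
                   speckle_shape = 4, n_microvessels = 6L,
                   n_side_branches = 2L, n_calcifications = 2L,
                   vessel_frames_min = 3L, vessel_frames_max = 12L),
    preprocess = list(catheter_radius_px = 12L, roi_depth = 300L,
                      kernel = 7L, sigma = 1, max_jump = 4L),
    augment = list(shift_alines = 55L, n_shifts = 9L,
                   include_original = TRUE,
                   rotation_angles = seq(30, 180, by = 30)),
    segment = list(base_channels = 8L, aspp_channels = 16L,
                   aspp_dilation_rates = NULL, threshold = NULL,
                   lr0 = 0.001, drop_factor = 0.2, drop_period = 0.5,
                   max_epochs = 50L, patience = 5L, min_rel_improve = 1e-4,
                   l2_weight = 1e-4, batch_size = 2L),
    classify = list(patch_side = 30L, patch_pad = 3L, min_area_px = 1L,
                    threshold = 0.5, lr0 = 0.001, drop_factor = 0.2,
                    drop_period = 0.5, max_epochs = 50L, batch_size = 32L),
    evaluate = list(n_folds = 5L, val_frac = 0.18),
    track = list(min_frames = 3L, min_overlap = 1L, lumen_depth_px = 2L))
}

#' Read / write a run configuration
#'
#' YAML on disk; missing keys fall back to [default_config()].
#' @param path YAML file path.
#' @param config configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}
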