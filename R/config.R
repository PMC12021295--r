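#' Default configuration
#'
#' Every tunable parameter of the pipeline lives in one nested list so that a
#' single file describes a reproducible run. The file representation is YAML
#' and round-trips losslessly.
#'
#' @section Groups:
#' * `preprocess`: `m` frames in the temporal background window (centered,
#'   truncated at the sequence ends), `background_stat` (`"mean"` or
#'   `"median"`), CLAHE clip limit and tile size, `register` toggle.
#' * `detect`: the LoG scale ladder `sigmas` (px), threshold weight `c`,
#'   ROI edge `roi_px`, classifier acceptance `p_min`, local-maxima
#'   separation and subpixel refinement controls.
#' * `link`: tracklet gates, tracklet-pair gates, Bayesian-network evidence
#'   discretization thresholds and odds table, assembly score cutoff and the
#'   per-pass overrides.
#' * `trajan`: moving-segment MSD window, exponent threshold and the sliding
#'   speed window (seconds).
#' * `evaluate`: point-match gate `epsilon_px` and `gamma_min_cover`.
#' * `synthetic`: generator defaults (see [scenario_params()]).
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    preprocess = list(m = 20L, background_stat = "mean",
                      clahe_clip = 0.01, clahe_tile_px = 32L,
                      register = FALSE),
    detect = list(sigmas = c(1.0, 1.5, 2.5, 4.0), c = 0.8, roi_px = 16L,
                  p_min = 0.99, min_peak_sep_px = 3, refine_iters = 20L,
                  refine_radius_px = 3L),
    link = list(max_link_dist_px = 5, max_missed_frames = 2L,
                max_tracklet_len = 10L, pair_gate_px = 15,
                pair_gate_frames = 5L, score_min = 0.5,
                bn = bn_default_params(),
                passes = list(list(pair_gate_px = 15))),
    trajan = list(msd_window = 5L, msd_exponent_min = 1.4,
                  speed_window_s = 1.0),
    evaluate = list(epsilon_px = 5, gamma_min_cover = 0.5),
    synthetic = list(T = 100L, H = 512L, W = 512L, density = "low",
                     snr = 7, psf_sigma_px = 1.3, background_level = 50,
                     n_distractors = 10L)
  )
}

#' Write a configuration to a YAML file
#' @param config nested parameter list as from [default_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config, precision = 15L), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Values are merged over [default_config()] so partial files are valid.
#'
#' @param path YAML file path.
#' @return Nested parameter list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  user <- yaml::yaml.load_file(path)
  modifyList(default_config(), user)
}
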