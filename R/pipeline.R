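#' Track a movie end to end
#'
#' Runs the full pipeline on an image sequence: preprocessing (temporal
#' background subtraction, contrast equalization, optional registration),
#' per-frame detection with classifier pruning and subpixel refinement,
#' tracklet formation, Bayesian-network tracklet linking (optionally in
#' multiple passes) and track filtering. All parameters come from the
#' configuration; the result carries a run manifest with per-stage counts
#' so a run is fully reproducible.
#'
#' @param seq an [image_sequence].
#' @param model a trained [train_classifier()] model (or `NULL` to skip
#'   classifier pruning).
#' @param config pipeline configuration, see [default_config()].
#' @param min_points,min_net_len_nm final track filters (0 disables the
#'   physical filter).
#' @param seed RNG seed recorded in the manifest; the pipeline itself is
#'   deterministic, the seed exists so downstream consumers can tie
#'   outputs to a run.
#' @param verbose print stage progress.
#' @return List with `tracks` (a [track_set()]), `detections`, and
#'   `manifest`.
#' @export
track_movie <- function(seq, model, config = default_config(),
                        min_points = 3, min_net_len_nm = 0, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(seq, "image_sequence"))
  set.seed(seed)
  shifts <- NULL
  if (isTRUE(config$preprocess$register)) {
    reg <- register_sequence(seq)
    seq <- reg$sequence
    shifts <- reg$shifts
  }
  dp <- do.call(detect_params, config$detect)
  det <- detect_sequence(seq, model, dp, config, verbose = verbose)
  if (verbose) message(nrow(det$detections), " detections")
  lp <- do.call(link_params, config$link)
  tracklets <- form_tracklets(det$detections, lp)
  if (verbose) message(length(tracklets), " tracklets")
  tracks <- multi_pass_link(tracklets, lp)
  if (verbose) message(length(tracks), " tracks")
  filtered <- filter_tracks(tracks, min_points = min_points,
                            min_net_len_nm = min_net_len_nm,
                            pixel_size_nm = seq$pixel_size_nm)
  for (i in seq_along(filtered)) filtered[[i]]$id <- i
  ts <- track_set(filtered, source = "vestrack pipeline",
                  pixel_size_nm = seq$pixel_size_nm,
                  frame_interval_s = seq$frame_interval_s)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vestrack")),
    config = config, seed = seed,
    input = list(frames = n_frames(seq), height = dim(seq$frames)[1],
                 width = dim(seq$frames)[2],
                 intensity_checksum = sum(seq$frames)),
    registration_shifts = shifts,
    counts = list(candidates = sum(det$counts$candidates),
                  accepted_detections = nrow(det$detections),
                  tracklets = length(tracklets),
                  tracks = length(tracks),
                  filtered_tracks = length(filtered)))
  list(tracks = ts, detections = det$detections, manifest = manifest)
}

#' Write a run manifest as JSON
#' @param manifest manifest list from [track_movie()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             path)
  invisible(path)
}
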