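#' Construct a track
#'
#' A track is an ordered run of detections with possible frame gaps: the unit
#' of linking output and analytics input.
#'
#' @param id track identifier (scalar, unique within a track set).
#' @param frames integer vector of 0-based frame indices, strictly increasing.
#' @param x,y numeric vectors of subpixel positions (pixels; `x` = column,
#'   `y` = row, 0-based).
#' @param brightness optional numeric vector of per-detection mean ROI
#'   intensity (raw counts); `NA` when unknown.
#' @param joins integer vector of linking pass indices, one per executed
#'   tracklet join (empty for unlinked tracks).
#' @return An object of class `vt_track`.
#' @export
new_track <- function(id, frames, x, y, brightness = NULL, joins = integer()) {
  n <- length(frames)
  if (length(x) != n || length(y) != n)
    stop("frames, x and y must have equal length")
  if (n > 1 && any(diff(frames) <= 0))
    stop("frame indices must be strictly increasing")
  if (is.null(brightness)) brightness <- rep(NA_real_, n)
  structure(list(id = id,
                 det = data.frame(frame = as.integer(frames),
                                  x = as.numeric(x), y = as.numeric(y),
                                  brightness = as.numeric(brightness)),
                 joins = as.integer(joins)),
            class = "vt_track")
}

track_len <- function(track) nrow(track$det)

#' Construct a track set
#'
#' @param tracks list of [new_track()] objects with unique ids.
#' @param source free-text provenance string.
#' @param pixel_size_nm,frame_interval_s sequence metadata carried along so
#'   physical quantities can be derived from a stored file.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks = list(), source = "",
                      pixel_size_nm = NULL, frame_interval_s = NULL) {
  ids <- vapply(tracks, function(t) as.character(t$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate track id: ", ids[duplicated(ids)][1])
  structure(list(tracks = tracks, source = source,
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d track(s)", length(x$tracks)))
  if (nzchar(x$source)) cat(" [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)

#' Write a track set to JSON
#'
#' Tracks are stored in pixel/frame units as
#' `{id, frames[], x[], y[], brightness[]}` records so files remain valid
#' without physical metadata. Coordinates are preserved to full double
#' precision and the writer is deterministic (no timestamps).
#'
#' @param tracks a [track_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  recs <- lapply(tracks$tracks, function(t) {
    list(id = t$id, frames = t$det$frame, x = t$det$x, y = t$det$y,
         brightness = t$det$brightness, joins = t$joins)
  })
  obj <- list(format = "vestrack-tracks-v1",
              source = tracks$source,
              pixel_size_nm = tracks$pixel_size_nm,
              frame_interval_s = tracks$frame_interval_s,
              tracks = recs)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a track set from JSON
#'
#' @param path file written by [write_tracks()] (or any file matching its
#'   schema).
#' @return A [track_set()].
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$tracks)) stop("malformed track file: no 'tracks' field")
  tracks <- lapply(obj$tracks, function(r) {
    br <- vapply(r$brightness, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                 numeric(1))
    new_track(id = r$id,
              frames = unlist(r$frames, use.names = FALSE),
              x = unlist(r$x, use.names = FALSE),
              y = unlist(r$y, use.names = FALSE),
              brightness = br,
              joins = as.integer(unlist(r$joins, use.names = FALSE)))
  })
  track_set(tracks,
            source = if (is.null(obj$source)) "" else obj$source,
            pixel_size_nm = num_or_null(obj$pixel_size_nm),
            frame_interval_s = num_or_null(obj$frame_interval_s))
}

#' Export per-track measures to CSV
#'
#' One row per track with the track id, frame span and every quantitative
#' trajectory measure. An empty measure list writes a header-only file.
#'
#' @param measures list of `trajectory_measures` objects, see
#'   [track_measures()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_measures_csv <- function(measures, path) {
  cols <- c("id", "first_frame", "last_frame", "n_detections",
            "d_total_um", "d_net_um", "d_max_um", "t_traj_s",
            "theta_net_deg", "b_mean", "v_curvilinear_um_s", "v_line_um_s",
            "v_max_segment_um_s", "k_segments", "t_avg_s")
  if (length(measures) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    rows <- lapply(measures, function(m) {
      as.data.frame(lapply(setNames(cols, cols), function(cn) {
        v <- m[[cn]]
        if (is.null(v)) NA else v
      }))
    })
    df <- do.call(rbind, rows)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
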