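#' Quantitative measures for one track
#'
#' Computes the standard per-trajectory measures: total, net and maximum
#' travelled distance, trajectory time, net orientation, normalized mean
#' brightness, mean curvilinear and straight-line speeds, sliding-window
#' maximum segment speed and moving-segment statistics. Physical units are
#' micrometres and seconds; frames missed inside the track (gaps) count
#' toward the trajectory time, otherwise speeds would be overestimated.
#'
#' @param track a `vt_track` with at least 2 detections.
#' @param frame_interval_s frame interval (s); required.
#' @param pixel_size_nm pixel size (nm); required.
#' @param b_max brightest pixel value of the image sequence, used to
#'   normalize the mean ROI brightness; when `NULL` the track's own maximum
#'   brightness is used.
#' @param config trajectory-analysis parameters (`trajan` group of
#'   [default_config()]).
#' @return Object of class `trajectory_measures`: a named list with
#'   `d_total_um`, `d_net_um`, `d_max_um` (largest distance from the start
#'   point), `t_traj_s`, `theta_net_deg` (0 = +x, 90 = up in the displayed
#'   image), `b_mean`, `v_curvilinear_um_s`, `v_line_um_s`,
#'   `v_max_segment_um_s`, `k_segments`, `t_avg_s`, plus id and frame-span
#'   bookkeeping.
#' @export
track_measures <- function(track, frame_interval_s, pixel_size_nm,
                           b_max = NULL, config = default_config()$trajan) {
  if (is.null(frame_interval_s) || is.null(pixel_size_nm))
    stop("physical measures require frame_interval_s and pixel_size_nm")
  d <- track$det
  n <- nrow(d)
  if (n < 2) stop("track needs at least 2 detections")
  um <- pixel_size_nm / 1000
  steps <- sqrt(diff(d$x)^2 + diff(d$y)^2) * um
  d_total <- sum(steps)
  d_net <- sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2) * um
  d_max <- max(sqrt((d$x - d$x[1])^2 + (d$y - d$y[1])^2)) * um
  t_traj <- (d$frame[n] - d$frame[1]) * frame_interval_s
  theta <- (atan2(-(d$y[n] - d$y[1]), d$x[n] - d$x[1]) * 180 / pi) %% 360
  if (is.null(b_max))
    b_max <- if (all(is.na(d$brightness))) NA_real_ else
      max(d$brightness, na.rm = TRUE)
  b_mean <- if (all(is.na(d$brightness)) || !is.finite(b_max) || b_max <= 0)
    NA_real_ else mean(d$brightness / b_max, na.rm = TRUE)

  seg <- segment_motion(track, config = config)
  vmax <- max_segment_speed(track, window_s = config$speed_window_s,
                            frame_interval_s = frame_interval_s,
                            pixel_size_nm = pixel_size_nm, segments = seg)
  structure(list(
    id = track$id, first_frame = d$frame[1], last_frame = d$frame[n],
    n_detections = n,
    d_total_um = d_total, d_net_um = d_net, d_max_um = d_max,
    t_traj_s = t_traj, theta_net_deg = theta, b_mean = b_mean,
    v_curvilinear_um_s = d_total / t_traj, v_line_um_s = d_net / t_traj,
    v_max_segment_um_s = vmax,
    k_segments = seg$k,
    t_avg_s = if (is.na(seg$k) || seg$k == 0) NA_real_ else
      mean(seg$segments$n_steps) * frame_interval_s
  ), class = "trajectory_measures")
}

#' Moving/paused segmentation of a track from rolling MSD exponents
#'
#' For each point, the mean squared displacement over lags 1-3 is computed
#' in a centered rolling window and its log-log slope taken as the local
#' diffusion exponent; points with exponent at or above the threshold
#' (default 1.4, between diffusive 1 and ballistic 2) are labeled moving.
#' Contiguous moving runs of at least 2 points become segments. Tracks
#' shorter than 5 points cannot be segmented this way and are flagged.
#'
#' @param track a `vt_track`.
#' @param config `trajan` parameter group (`msd_window`,
#'   `msd_exponent_min`).
#' @return List with `labels` (`"moving"` / `"paused"` per detection, or
#'   `"unsegmentable"`), `exponent` (per-point slope), `k` (number of
#'   moving segments, `NA` when unsegmentable) and `segments` (data frame
#'   with `start`, `end` point indices and `n_steps`).
#' @export
segment_motion <- function(track, config = default_config()$trajan) {
  d <- track$det
  n <- nrow(d)
  w <- config$msd_window
  if (n < 5) {
    return(list(labels = rep("unsegmentable", n),
                exponent = rep(NA_real_, n), k = NA_integer_,
                segments = data.frame(start = integer(0), end = integer(0),
                                      n_steps = integer(0))))
  }
  half <- (w - 1) %/% 2
  expo <- numeric(n)
  lags <- 1:3
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    if (hi - lo + 1 < w) {            # slide the window inward at the ends
      lo <- max(1, min(lo, n - w + 1)); hi <- min(n, lo + w - 1)
    }
    msd <- vapply(lags, function(L) {
      j <- lo:(hi - L)
      if (length(j) == 0) return(NA_real_)
      mean((d$x[j + L] - d$x[j])^2 + (d$y[j + L] - d$y[j])^2)
    }, numeric(1))
    ok <- !is.na(msd) & msd > 0
    expo[i] <- if (sum(ok) < 2) 0 else
      stats::coef(stats::lm(log(msd[ok]) ~ log(lags[ok])))[2]
  }
  labels <- ifelse(expo >= config$msd_exponent_min, "moving", "paused")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- data.frame(start = starts[r$values == "moving"],
                     end = ends[r$values == "moving"])
  segs <- segs[segs$end - segs$start >= 1, , drop = FALSE]  # >= 2 points
  segs$n_steps <- segs$end - segs$start
  rownames(segs) <- NULL
  list(labels = labels, exponent = expo, k = nrow(segs), segments = segs)
}

#' Maximum curvilinear speed over a sliding window
#'
#' Slides a window of `round(window_s / frame_interval_s)` frame intervals
#' over the moving segments of the track and returns the maximum of path
#' length divided by window time, among windows fully inside one moving
#' segment. Flagged `NA` when no moving segment is long enough.
#'
#' @param track a `vt_track`.
#' @param window_s window length in seconds (default 1 s).
#' @param frame_interval_s frame interval (s).
#' @param pixel_size_nm pixel size (nm).
#' @param segments optional precomputed [segment_motion()] result; tracks
#'   flagged unsegmentable fall back to one whole-track segment.
#' @return Maximum windowed curvilinear speed in um/s, or `NA`.
#' @export
max_segment_speed <- function(track, window_s = 1, frame_interval_s,
                              pixel_size_nm, segments = NULL) {
  if (window_s < frame_interval_s) stop("window_s must be >= frame_interval_s")
  d <- track$det
  n <- nrow(d)
  if (n < 2) return(NA_real_)
  if (is.null(segments)) segments <- segment_motion(track)
  segs <- segments$segments
  if (is.na(segments$k))
    segs <- data.frame(start = 1, end = n, n_steps = n - 1)
  if (nrow(segs) == 0) return(NA_real_)
  w <- max(1L, round(window_s / frame_interval_s))
  um <- pixel_size_nm / 1000
  steps <- sqrt(diff(d$x)^2 + diff(d$y)^2) * um      # step i: point i -> i+1
  step_frames <- diff(d$frame)
  best <- NA_real_
  for (s in seq_len(nrow(segs))) {
    first <- segs$start[s]; last <- segs$end[s]
    # windows of w frame intervals over detections [first, last]
    for (i in first:(last - 1)) {
      j <- i
      span <- 0L; len <- 0
      while (j <= last - 1 && span + step_frames[j] <= w) {
        span <- span + step_frames[j]; len <- len + steps[j]; j <- j + 1
      }
      if (span == w) {
        v <- len / (w * frame_interval_s)
        if (is.na(best) || v > best) best <- v
      }
    }
  }
  best
}

#' Classify a track direction against a tissue axis
#'
#' Net track headings within 45 degrees of the reference axis are classed
#' with the axis (`apical` or `leading`), within 45 degrees of the
#' opposite direction against it (`basal` / `trailing`), and the two
#' remaining 90-degree quadrants are `lateral` (`perpendicular`). Ties at
#' exactly 45 degrees go to the axial class.
#'
#' @param theta_net_deg net track orientation (deg, 0 = +x, 90 = up).
#' @param axis_angle_deg direction of the apical (or leading) axis.
#' @param labels the three class names, axial first.
#' @return Character class label.
#' @export
classify_direction <- function(theta_net_deg, axis_angle_deg = 90,
                               labels = c("apical", "lateral", "basal")) {
  dang <- abs(((theta_net_deg - axis_angle_deg + 180) %% 360) - 180)
  ifelse(dang <= 45, labels[1], ifelse(dang >= 135, labels[3], labels[2]))
}

#' Polar histogram of track orientations
#'
#' Bins net track orientations into 10-degree sectors, excluding tracks
#' whose net displacement is below `min_net_um` (1 um by default), and
#' reports raw counts, counts per minute of movie time and per-bin summed
#' net distances.
#'
#' @param measures list of [track_measures()] results.
#' @param duration_min movie duration in minutes (> 0).
#' @param min_net_um minimum net distance for inclusion (um).
#' @return Data frame with `bin_start`, `bin_end`, `count`,
#'   `count_per_min` and `net_distance_sum_um`; 36 rows partitioning
#'   `[0, 360)`.
#' @export
polar_histogram <- function(measures, duration_min, min_net_um = 1) {
  if (duration_min <= 0) stop("duration_min must be positive")
  theta <- vapply(measures, `[[`, numeric(1), "theta_net_deg")
  dnet <- vapply(measures, `[[`, numeric(1), "d_net_um")
  keep <- dnet >= min_net_um
  theta <- theta[keep] %% 360
  dnet <- dnet[keep]
  bin <- floor(theta / 10) + 1
  out <- data.frame(bin_start = seq(0, 350, by = 10),
                    bin_end = seq(10, 360, by = 10))
  out$count <- tabulate(bin, nbins = 36)
  out$count_per_min <- out$count / duration_min
  out$net_distance_sum_um <- vapply(seq_len(36), function(b)
    sum(dnet[bin == b]), numeric(1))
  out
}

#' Net displacement of a track along a tissue axis
#'
#' Projects the net displacement vector onto the unit vector of the apical
#' (or leading-edge) direction; positive values point toward the axis
#' direction.
#'
#' @param track a `vt_track`.
#' @param axis_angle_deg axis direction (deg, 0 = +x, 90 = up).
#' @param pixel_size_nm pixel size (nm); required.
#' @return Signed displacement in micrometres.
#' @export
axis_displacement <- function(track, axis_angle_deg = 90, pixel_size_nm) {
  if (is.null(pixel_size_nm)) stop("axis_displacement requires pixel_size_nm")
  d <- track$det
  n <- nrow(d)
  vx <- d$x[n] - d$x[1]
  vy <- -(d$y[n] - d$y[1])      # display convention: up is positive
  a <- axis_angle_deg * pi / 180
  (vx * cos(a) + vy * sin(a)) * pixel_size_nm / 1000
}

#' Per-frame Pearson correlation between two image sequences
#'
#' Computes the Pearson correlation of pixel intensities between the two
#' channels in every frame, the change in correlation relative to a
#' reference time point and that change normalized to `[0, 1]` by its
#' maximum `K`, the form used for cargo/marker colocalization time
#' courses.
#'
#' @param seq_a,seq_b [image_sequence] objects with identical shape.
#' @param reference `"first"` (default) or `"last"`: the time point whose
#'   delta is anchored at 0.
#' @return Data frame with `frame`, `r` (`NA` and `undefined = TRUE` for
#'   zero-variance frames), `delta` and `normalized`.
#' @export
framewise_pearson <- function(seq_a, seq_b, reference = c("first", "last")) {
  reference <- match.arg(reference)
  if (!identical(dim(seq_a$frames), dim(seq_b$frames)))
    stop("sequences must have identical shape")
  T <- n_frames(seq_a)
  r <- vapply(seq_len(T), function(t) {
    a <- as.vector(seq_a$frames[, , t]); b <- as.vector(seq_b$frames[, , t])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  ref_idx <- if (reference == "first") which(!is.na(r))[1] else
    rev(which(!is.na(r)))[1]
  delta <- r - r[ref_idx]
  K <- max(delta, na.rm = TRUE)
  normalized <- if (is.finite(K) && K > 0) delta / K else
    ifelse(is.na(delta), NA_real_, 0)
  data.frame(frame = 0:(T - 1), r = r, undefined = is.na(r),
             delta = delta, normalized = normalized)
}
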