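#' Linking parameters
#'
#' @param max_link_dist_px gate for detection-to-tracklet growth (px).
#' @param max_missed_frames consecutive frames a tracklet may go undetected
#'   before it is closed.
#' @param max_tracklet_len length cap; a tracklet reaching it is closed and
#'   a successor opened (the join is recovered at the tracklet-linking
#'   stage).
#' @param pair_gate_px,pair_gate_frames spatial / temporal window within
#'   which a tracklet pair is scored at all.
#' @param score_min minimum connectivity probability for a join.
#' @param bn Bayesian-network parameters, see [bn_default_params()].
#' @param passes list of per-pass overrides for multi-pass linking (each a
#'   named list of the above, typically a growing `pair_gate_px`).
#' @return Named list of linking parameters.
#' @export
link_params <- function(max_link_dist_px = 5, max_missed_frames = 2L,
                        max_tracklet_len = 10L, pair_gate_px = 15,
                        pair_gate_frames = 5L, score_min = 0.5,
                        bn = bn_default_params(),
                        passes = list(list())) {
  stopifnot(max_link_dist_px > 0, pair_gate_px > 0, pair_gate_frames > 0)
  list(max_link_dist_px = max_link_dist_px,
       max_missed_frames = as.integer(max_missed_frames),
       max_tracklet_len = as.integer(max_tracklet_len),
       pair_gate_px = pair_gate_px,
       pair_gate_frames = as.integer(pair_gate_frames),
       score_min = score_min, bn = bn, passes = passes)
}

#' Form tracklets from frame-wise detections
#'
#' Processes frames sequentially: open tracklets are matched to the current
#' frame's detections by Euclidean distance from their last position using
#' the gated Hungarian assignment; unmatched detections open new tracklets;
#' tracklets missing for more than `max_missed_frames` consecutive frames
#' are closed, and tracklets reaching `max_tracklet_len` are closed with a
#' successor continuing from the same position.
#'
#' @param detections data frame with `frame`, `x`, `y` and optionally
#'   `roi_mean` (any other columns are carried along), sorted by frame.
#' @param params a [link_params()] list.
#' @return List of tracks (class `vt_track`), each a tracklet.
#' @export
form_tracklets <- function(detections, params = link_params()) {
  req <- c("frame", "x", "y")
  if (!all(req %in% names(detections))) stop("detections need frame, x, y")
  if (!"roi_mean" %in% names(detections)) detections$roi_mean <- NA_real_
  detections <- detections[order(detections$frame), , drop = FALSE]
  done <- list()
  open <- list()  # each: list(rows = list of detection rows, last_x/y/frame)
  next_id <- 1L
  close_tracklet <- function(tl) {
    if (length(tl$rows) == 0) return(invisible())
    df <- do.call(rbind, tl$rows)
    done[[length(done) + 1]] <<- new_track(tl$id, df$frame, df$x, df$y,
                                           brightness = df$roi_mean)
  }
  for (f in sort(unique(detections$frame))) {
    # close tracklets that have been missing too long
    if (length(open)) {
      stale <- vapply(open, function(tl)
        f - tl$last_frame > params$max_missed_frames + 1L, logical(1))
      for (tl in open[stale]) close_tracklet(tl)
      open <- open[!stale]
    }
    det_f <- detections[detections$frame == f, , drop = FALSE]
    matched_det <- integer(0)
    if (length(open) && nrow(det_f)) {
      lx <- vapply(open, `[[`, numeric(1), "last_x")
      ly <- vapply(open, `[[`, numeric(1), "last_y")
      costs <- sqrt(outer(lx, det_f$x, "-")^2 + outer(ly, det_f$y, "-")^2)
      # restrict the assignment to tracklets/detections with at least one
      # in-gate partner; the rest are unmatched by definition
      adm <- costs <= params$max_link_dist_px
      rsub <- which(rowSums(adm) > 0)
      csub <- which(colSums(adm) > 0)
      as_res <- solve_assignment(costs[rsub, csub, drop = FALSE],
                                 gate = params$max_link_dist_px)
      as_res$matches <- cbind(row = rsub[as_res$matches[, 1]],
                              col = csub[as_res$matches[, 2]])
      for (m in seq_len(nrow(as_res$matches))) {
        i <- as_res$matches[m, 1]; j <- as_res$matches[m, 2]
        row <- det_f[j, c("frame", "x", "y", "roi_mean"), drop = FALSE]
        open[[i]]$rows <- c(open[[i]]$rows, list(row))
        open[[i]]$last_x <- row$x; open[[i]]$last_y <- row$y
        open[[i]]$last_frame <- row$frame
      }
      matched_det <- as_res$matches[, 2]
    }
    for (j in setdiff(seq_len(nrow(det_f)), matched_det)) {
      row <- det_f[j, c("frame", "x", "y", "roi_mean"), drop = FALSE]
      open[[length(open) + 1]] <- list(id = next_id, rows = list(row),
                                       last_x = row$x, last_y = row$y,
                                       last_frame = row$frame)
      next_id <- next_id + 1L
    }
    # cap tracklet length: close and open an (empty) successor that keeps
    # the position so the particle is not lost
    if (length(open)) {
      full <- vapply(open, function(tl)
        length(tl$rows) >= params$max_tracklet_len, logical(1))
      for (i in which(full)) {
        close_tracklet(open[[i]])
        open[[i]]$rows <- list()
        open[[i]]$id <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  for (tl in open) close_tracklet(tl)
  done
}

# heading (deg, display convention: 0 = +x, 90 = up) and speed (px/frame)
# of the terminal segment of a tracklet; NULL for single-point tracklets
terminal_segment <- function(track, end = c("last", "first")) {
  end <- match.arg(end)
  d <- track$det
  if (nrow(d) < 2) return(NULL)
  i <- if (end == "last") c(nrow(d) - 1, nrow(d)) else c(1, 2)
  dx <- d$x[i[2]] - d$x[i[1]]
  dy <- d$y[i[2]] - d$y[i[1]]
  dt <- d$frame[i[2]] - d$frame[i[1]]
  list(heading = atan2(-dy, dx) * 180 / pi,
       speed = sqrt(dx^2 + dy^2) / dt)
}

ord3 <- function(value, cuts) {
  c("good", "mid", "poor")[findInterval(value, cuts) + 1]
}

#' Evidence for one tracklet pair
#'
#' Computes and discretizes the Bayesian-network evidence for an ordered
#' pair of tracklets `(a, b)`: intensity ratio of the terminal ROI means,
#' heading difference and speed ratio of the terminal segments, order and
#' overlap of the frame ranges, frame gap and end-to-start distance.
#' Length-1 tracklets yield the `unknown` state for orientation and speed.
#'
#' @param a,b `vt_track` tracklets (`a` is the candidate predecessor).
#' @param params a [link_params()] list.
#' @return Named list of evidence states plus the raw `gap` and `dist`.
#' @export
tracklet_evidence <- function(a, b, params = link_params()) {
  th <- params$bn$thresholds
  pa <- a$det[nrow(a$det), ]; pb <- b$det[1, ]
  gap <- pb$frame - pa$frame - 1L
  dist <- sqrt((pb$x - pa$x)^2 + (pb$y - pa$y)^2)
  od <- pb$frame > pa$frame
  ov <- pb$frame <= pa$frame     # b starts before a has ended
  ia <- pa$brightness; ib <- pb$brightness
  ev_I <- if (is.na(ia) || is.na(ib) || min(ia, ib) <= 0) "unknown" else
    ord3(max(ia, ib) / min(ia, ib), th$intensity_ratio)
  sa <- terminal_segment(a, "last"); sb <- terminal_segment(b, "first")
  if (is.null(sa) || is.null(sb)) {
    ev_Or <- "unknown"; ev_Sp <- "unknown"
  } else {
    dang <- abs(((sa$heading - sb$heading + 180) %% 360) - 180)
    ev_Or <- ord3(dang, th$angle_deg)
    ev_Sp <- if (min(sa$speed, sb$speed) == 0) {
      if (max(sa$speed, sb$speed) == 0) "good" else "poor"
    } else ord3(max(sa$speed, sb$speed) / min(sa$speed, sb$speed),
                th$speed_ratio)
  }
  list(I = ev_I, Or = ev_Or, Sp = ev_Sp,
       Od = if (od) "TRUE" else "FALSE",
       Ov = if (ov) "TRUE" else "FALSE",
       G = ord3(max(gap, 0), th$gap_frames),
       D = ord3(dist / params$pair_gate_px, th$dist_frac),
       gap = gap, dist = dist)
}

#' Connectivity score for a tracklet pair
#'
#' Pairs separated by more than `pair_gate_px` in space or
#' `pair_gate_frames` in time are not comparable (returns `NULL`): the
#' score is only computed for tracklets close in space and time. Otherwise
#' the evidence is discretized and exact inference on the discrete network
#' returns the probability that the pair belongs to one trajectory.
#'
#' @param a,b `vt_track` tracklets (`a` the candidate predecessor).
#' @param params a [link_params()] list.
#' @param net prebuilt network from `bn_build(params$bn)` (rebuilt when
#'   omitted; pass it when scoring many pairs).
#' @return List with `p_c` and the evidence, or `NULL` if not comparable.
#' @export
score_pair <- function(a, b, params = link_params(), net = NULL) {
  ev <- tracklet_evidence(a, b, params)
  if (ev$dist > params$pair_gate_px) return(NULL)
  if (ev$gap > params$pair_gate_frames) return(NULL)
  if (ev$gap < -params$pair_gate_frames) return(NULL)
  if (is.null(net)) net <- bn_build(params$bn)
  post <- bn_infer(net, "CS",
                   evidence = ev[c("I", "Or", "Sp", "Od", "Ov", "G", "D")])
  list(p_c = unname(post[["TRUE"]]), evidence = ev)
}

#' Assemble tracklets into tracks
#'
#' Scores every comparable ordered tracklet pair, then solves one
#' predecessor/successor assignment with the Hungarian algorithm using
#' cost `1 - P_c` gated at `1 - score_min`; chains of joins are
#' concatenated into tracks and unchained tracklets become single-tracklet
#' tracks. Only pairs that do not overlap in time are eligible for an
#' executed join, so detections are conserved and frames stay strictly
#' increasing.
#'
#' @param tracklets list of `vt_track`.
#' @param params a [link_params()] list.
#' @param pass_index recorded on each executed join.
#' @return List of `vt_track` tracks.
#' @export
link_tracklets <- function(tracklets, params = link_params(),
                           pass_index = 1L) {
  n <- length(tracklets)
  if (n <= 1) return(tracklets)
  net <- bn_build(params$bn)
  starts <- vapply(tracklets, function(t) t$det$frame[1], numeric(1))
  ends <- vapply(tracklets, function(t) t$det$frame[nrow(t$det)], numeric(1))
  ex <- vapply(tracklets, function(t) t$det$x[nrow(t$det)], numeric(1))
  ey <- vapply(tracklets, function(t) t$det$y[nrow(t$det)], numeric(1))
  sx <- vapply(tracklets, function(t) t$det$x[1], numeric(1))
  sy <- vapply(tracklets, function(t) t$det$y[1], numeric(1))

  # find admissible (gated) pairs first; the assignment then only involves
  # tracklets with at least one partner, keeping the Hungarian problem
  # small even when many isolated spurious tracklets exist
  pair_i <- integer(0); pair_j <- integer(0); pair_cost <- numeric(0)
  for (i in seq_len(n)) {
    gaps <- starts - ends[i] - 1
    dd <- sqrt((sx - ex[i])^2 + (sy - ey[i])^2)
    cand <- which(gaps >= 0 & gaps <= params$pair_gate_frames &
                    dd <= params$pair_gate_px)
    cand <- setdiff(cand, i)
    for (j in cand) {
      sc <- score_pair(tracklets[[i]], tracklets[[j]], params, net)
      if (!is.null(sc) && sc$p_c >= params$score_min) {
        pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        pair_cost <- c(pair_cost, 1 - sc$p_c)
      }
    }
  }
  succ <- rep(NA_integer_, n)
  has_pred <- logical(n)
  if (length(pair_i)) {
    rows <- sort(unique(pair_i)); cols <- sort(unique(pair_j))
    costs <- matrix(2, length(rows), length(cols))
    costs[cbind(match(pair_i, rows), match(pair_j, cols))] <- pair_cost
    res <- solve_assignment(costs, gate = 1 - params$score_min)
    for (m in seq_len(nrow(res$matches))) {
      i <- rows[res$matches[m, 1]]; j <- cols[res$matches[m, 2]]
      succ[i] <- j
      has_pred[j] <- TRUE
    }
  }
  roots <- which(!has_pred)
  out <- vector("list", length(roots))
  for (r in seq_along(roots)) {
    chain <- roots[r]
    while (!is.na(succ[chain[length(chain)]])) {
      nxt <- succ[chain[length(chain)]]
      if (nxt %in% chain) stop("cyclic tracklet chain")  # unreachable: joins are time-ordered
      chain <- c(chain, nxt)
    }
    dets <- do.call(rbind, lapply(tracklets[chain], function(t) t$det))
    joins <- c(unlist(lapply(tracklets[chain], function(t) t$joins)),
               rep(pass_index, length(chain) - 1))
    out[[r]] <- new_track(tracklets[[chain[1]]]$id, dets$frame, dets$x,
                          dets$y, dets$brightness, joins = joins)
  }
  out
}

#' Multi-pass track linking
#'
#' Re-runs tracklet scoring and assembly on the current track set once per
#' pass, each pass with its own parameter overrides — typically a growing
#' distance gate, so a first pass connects slow-moving particles and a
#' second pass the faster ones. The pass index is recorded on every join.
#'
#' @param tracklets list of `vt_track` (tracklets or tracks).
#' @param params a [link_params()] list whose `passes` element holds one
#'   named list of overrides per pass.
#' @return List of `vt_track` tracks.
#' @export
multi_pass_link <- function(tracklets, params = link_params()) {
  passes <- params$passes
  if (length(passes) == 0) passes <- list(list())
  cur <- tracklets
  for (p in seq_along(passes)) {
    pp <- modifyList(params, passes[[p]])
    cur <- link_tracklets(cur, pp, pass_index = p)
  }
  cur
}

#' Filter tracks by size and physical net length
#'
#' @param tracks list of `vt_track`.
#' @param min_points minimum number of detections.
#' @param min_net_len_nm minimum net (start-to-end) length in nanometres;
#'   requires `pixel_size_nm`. Vesicle studies typically drop tracks below
#'   700 nm before curation and below 1000 nm before analysis.
#' @param pixel_size_nm physical pixel size (nm).
#' @return Filtered list of tracks.
#' @export
filter_tracks <- function(tracks, min_points = 1, min_net_len_nm = 0,
                          pixel_size_nm = NULL) {
  if (min_net_len_nm > 0 && is.null(pixel_size_nm))
    stop("min_net_len_nm requires pixel_size_nm")
  keep <- vapply(tracks, function(t) {
    if (nrow(t$det) < min_points) return(FALSE)
    if (min_net_len_nm > 0) {
      d <- t$det
      net_px <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
      if (net_px * pixel_size_nm < min_net_len_nm) return(FALSE)
    }
    TRUE
  }, logical(1))
  tracks[keep]
}
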