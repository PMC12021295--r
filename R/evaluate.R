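#' Pairing parameters for track evaluation
#'
#' @param epsilon_px point-match gate: a ground-truth and estimated point
#'   in the same frame match when closer than this, and it is also the
#'   per-frame penalty charged for unmatched points (default 5 px).
#' @param gamma_min_cover fraction of a ground-truth track's points that
#'   must be matched for the track to count as recovered (default 0.5).
#' @return Named list of parameters.
#' @export
pairing_params <- function(epsilon_px = 5, gamma_min_cover = 0.5) {
  stopifnot(epsilon_px > 0, gamma_min_cover > 0, gamma_min_cover <= 1)
  list(epsilon_px = epsilon_px, gamma_min_cover = gamma_min_cover)
}

# gated track-to-track distance: sum over the union of the two frame sets
# of min(point distance, eps), with eps charged for frames where either
# track lacks a point
track_distance <- function(g, e, eps) {
  fg <- g$det$frame; fe <- e$det$frame
  common <- intersect(fg, fe)
  d <- 0
  if (length(common)) {
    ig <- match(common, fg); ie <- match(common, fe)
    dd <- sqrt((g$det$x[ig] - e$det$x[ie])^2 + (g$det$y[ig] - e$det$y[ie])^2)
    d <- sum(pmin(dd, eps))
  }
  d + eps * (length(fg) - length(common)) + eps * (length(fe) - length(common))
}

matched_points <- function(g, e, eps) {
  common <- intersect(g$det$frame, e$det$frame)
  if (!length(common)) return(data.frame(frame = integer(0), dist = numeric(0)))
  ig <- match(common, g$det$frame); ie <- match(common, e$det$frame)
  dd <- sqrt((g$det$x[ig] - e$det$x[ie])^2 + (g$det$y[ig] - e$det$y[ie])^2)
  data.frame(frame = common, dist = dd)[dd <= eps, , drop = FALSE]
}

#' Pair ground-truth and estimated tracks
#'
#' Builds the optimal one-to-one pairing between ground-truth and estimated
#' tracks that minimizes the total gated track distance (sum over the union
#' of frames of the point distance capped at `epsilon_px`, with the cap
#' charged for frames where either track has no point). Pairing an
#' estimated track is only ever accepted when it beats leaving the
#' ground-truth track unpaired, and pairs in which no point ever matches
#' within the gate are dissolved. For tractability only candidate pairs
#' overlapping in time with centroids within `prefilter_px` are scored.
#'
#' @param gt,est [track_set()] objects in the same coordinate space.
#' @param params a [pairing_params()] list.
#' @param prefilter_px centroid distance pre-filter (px).
#' @return List of class `track_pairing` with `pairs` (data frame: `gt`,
#'   `est` list indices, `distance`, `matched` point count), indices of
#'   `unpaired_gt` and `spurious_est`, and the parameters used.
#' @export
pair_tracks <- function(gt, est, params = pairing_params(),
                        prefilter_px = 50) {
  eps <- params$epsilon_px
  ng <- length(gt$tracks); ne <- length(est$tracks)
  empty_cost <- function(t) eps * nrow(t$det)
  if (ng == 0 || ne == 0) {
    return(structure(list(
      pairs = data.frame(gt = integer(0), est = integer(0),
                         distance = numeric(0), matched = integer(0)),
      unpaired_gt = seq_len(ng), spurious_est = seq_len(ne),
      params = params), class = "track_pairing"))
  }
  cen <- function(t) c(mean(t$det$x), mean(t$det$y))
  gc <- vapply(gt$tracks, cen, numeric(2))
  ec <- vapply(est$tracks, cen, numeric(2))
  gr <- vapply(gt$tracks, function(t) range(t$det$frame), numeric(2))
  er <- vapply(est$tracks, function(t) range(t$det$frame), numeric(2))

  # cost of pairing g with e, and per-gt "leave unpaired" dummy columns;
  # the assignment then minimizes the total evaluation distance
  big <- eps * (max(colSums(rbind(gr[2, ] - gr[1, ] + 1,
                                  rep(max(er[2, ] - er[1, ] + 1), ng)))) + 10)
  costs <- matrix(big, ng, ne + ng)
  for (i in seq_len(ng)) {
    for (j in seq_len(ne)) {
      if (er[1, j] > gr[2, i] || er[2, j] < gr[1, i]) next
      if (sum((gc[, i] - ec[, j])^2) > prefilter_px^2) next
      costs[i, j] <- track_distance(gt$tracks[[i]], est$tracks[[j]], eps)
    }
    costs[i, ne + i] <- empty_cost(gt$tracks[[i]])
  }
  res <- solve_assignment(costs)
  pairs <- data.frame(gt = integer(0), est = integer(0),
                      distance = numeric(0), matched = integer(0))
  for (m in seq_len(nrow(res$matches))) {
    i <- res$matches[m, 1]; j <- res$matches[m, 2]
    if (j > ne) next                               # paired with its dummy
    if (costs[i, j] >= big) next
    mp <- matched_points(gt$tracks[[i]], est$tracks[[j]], eps)
    if (nrow(mp) == 0) next                        # worst case: dissolve
    pairs <- rbind(pairs, data.frame(gt = i, est = j,
                                     distance = costs[i, j],
                                     matched = nrow(mp)))
  }
  structure(list(pairs = pairs,
                 unpaired_gt = setdiff(seq_len(ng), pairs$gt),
                 spurious_est = setdiff(seq_len(ne), pairs$est),
                 params = params),
            class = "track_pairing")
}

#' Tracking performance metrics from a track pairing
#'
#' Computes the standard linking measures: `alpha` (degree of matching
#' between ground truth and estimate, ignoring spurious tracks; 1 is
#' perfect), `beta` (like alpha but with a penalty for spurious estimated
#' tracks, so `0 <= beta <= alpha`), the Jaccard similarity for track
#' points `jsc` and for entire tracks `jsc_theta`, the localization
#' `rmse_px` over matched point pairs, and `gamma`, the fraction of
#' ground-truth tracks recovered (paired with at least `gamma_min_cover`
#' of their points matched within the gate).
#'
#' @param gt,est the [track_set()] pair used to build the pairing.
#' @param pairing a [pair_tracks()] result.
#' @return Object of class `evaluation_report`: a named list with the six
#'   measures and the raw TP/FN/FP point and track counts.
#' @export
compute_metrics <- function(gt, est, pairing) {
  eps <- pairing$params$epsilon_px
  ng <- length(gt$tracks)
  if (ng == 0) stop("empty ground truth: metrics undefined")
  gt_sizes <- vapply(gt$tracks, function(t) nrow(t$det), numeric(1))
  est_sizes <- vapply(est$tracks, function(t) nrow(t$det), numeric(1))
  d_empty <- eps * sum(gt_sizes)

  pr <- pairing$pairs
  d_match <- sum(pr$distance) + eps * sum(gt_sizes[pairing$unpaired_gt])
  d_spur <- eps * sum(est_sizes[pairing$spurious_est])

  alpha <- 1 - d_match / d_empty
  beta <- (d_empty - d_match) / (d_empty + d_spur)

  tp <- sum(pr$matched)
  fn <- sum(gt_sizes) - tp
  fp <- sum(est_sizes) - tp
  jsc <- if (tp + fn + fp == 0) NA_real_ else tp / (tp + fn + fp)
  jsc_theta <- nrow(pr) /
    (nrow(pr) + length(pairing$unpaired_gt) + length(pairing$spurious_est))

  sq <- 0; nm <- 0
  for (m in seq_len(nrow(pr))) {
    mp <- matched_points(gt$tracks[[pr$gt[m]]], est$tracks[[pr$est[m]]], eps)
    sq <- sq + sum(mp$dist^2); nm <- nm + nrow(mp)
  }
  rmse <- if (nm == 0) NA_real_ else sqrt(sq / nm)

  covered <- pr$matched >= pairing$params$gamma_min_cover * gt_sizes[pr$gt]
  gamma <- sum(covered) / ng

  structure(list(alpha = alpha, beta = beta, jsc = jsc,
                 jsc_theta = jsc_theta, rmse_px = rmse, gamma = gamma,
                 tp_points = tp, fn_points = fn, fp_points = fp,
                 paired_tracks = nrow(pr),
                 unpaired_gt_tracks = length(pairing$unpaired_gt),
                 spurious_est_tracks = length(pairing$spurious_est)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation: alpha %.3f  beta %.3f  JSC %.3f  ",
                     "JSC_theta %.3f  RMSE %.3f px  gamma %.3f\n"),
              x$alpha, x$beta, x$jsc, x$jsc_theta, x$rmse_px, x$gamma))
  invisible(x)
}

#' Evaluate an estimated track file against ground truth
#'
#' Reads both track files, pairs and scores them and optionally writes a
#' JSON report with the parameters embedded. Tracks are compared on the
#' intersection of their frame ranges (a warning is raised when the ranges
#' differ).
#'
#' @param gt_path,est_path JSON track files ([write_tracks()] format).
#' @param params a [pairing_params()] list.
#' @param report_path optional path for the JSON report.
#' @return The `evaluation_report`, invisibly when writing a report.
#' @export
evaluate_run <- function(gt_path, est_path, params = pairing_params(),
                         report_path = NULL) {
  gt <- read_tracks(gt_path)
  est <- read_tracks(est_path)
  frange <- function(ts) range(unlist(lapply(ts$tracks,
                                             function(t) t$det$frame)))
  if (length(gt$tracks) && length(est$tracks) &&
      !identical(frange(gt), frange(est)))
    warning("frame ranges differ; evaluating on their intersection")
  pairing <- pair_tracks(gt, est, params)
  rep <- compute_metrics(gt, est, pairing)
  if (!is.null(report_path)) {
    obj <- c(list(parameters = params), unclass(rep))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), report_path)
    return(invisible(rep))
  }
  rep
}
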