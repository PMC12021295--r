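#' Detection parameters
#'
#' @param sigmas strictly increasing LoG scale ladder (px); each scale
#'   prefers spots of radius about `sigma * sqrt(2)`.
#' @param c threshold weight: each filter iteration keeps pixels above
#'   `mean + c * sd` of its response image.
#' @param roi_px even classifier patch edge (default 16).
#' @param p_min classifier acceptance probability in (0, 1).
#' @param min_peak_sep_px minimum separation between candidate peaks; closer
#'   peaks are merged keeping the higher response.
#' @param refine_iters,refine_radius_px iteration cap and window radius of
#'   the center-of-mass refinement.
#' @return Named list of validated detection parameters.
#' @export
detect_params <- function(sigmas = c(1.0, 1.5, 2.5, 4.0), c = 0.8,
                          roi_px = 16L, p_min = 0.99, min_peak_sep_px = 3,
                          refine_iters = 20L, refine_radius_px = 3L) {
  if (length(sigmas) == 0) stop("empty sigmas")
  if (any(sigmas <= 0) || any(diff(sigmas) <= 0))
    stop("sigmas must be strictly increasing and positive")
  if (p_min <= 0 || p_min >= 1) stop("p_min must lie in (0, 1)")
  list(sigmas = sigmas, c = c, roi_px = as.integer(roi_px), p_min = p_min,
       min_peak_sep_px = min_peak_sep_px,
       refine_iters = as.integer(refine_iters),
       refine_radius_px = as.integer(refine_radius_px))
}

#' Scale-normalized Laplacian-of-Gaussian kernel
#'
#' Negated and multiplied by `sigma^2` so that bright blobs of matching
#' scale give positive peaks of comparable height across the scale ladder;
#' the kernel is shifted to zero mean so a constant image maps to zero.
#'
#' @param sigma kernel standard deviation (px).
#' @return Odd-sized square matrix kernel.
#' @export
log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  g <- -r:r
  d2 <- outer(g^2, g^2, "+")
  k <- -sigma^2 * (d2 - 2 * sigma^2) / (2 * pi * sigma^6) *
    exp(-d2 / (2 * sigma^2))
  k - mean(k)
}

#' Multiscale spot-enhancing filter
#'
#' Iterates the spot-enhancing filter over the scale ladder: at iteration
#' `k` the image masked by the previous binary mask is convolved with the
#' scale-`k` LoG, `f = LoG(sigma_k) * (b_{k-1} g)` with `b_0 = 1`; the mask
#' is then updated to `f > T_k` with `T_k = mu_k + c * s_k`, where `mu_k`
#' and `s_k` are the mean and standard deviation of the whole response
#' image. The final response and mask expose spots of varying size and
#' brightness while suppressing noise.
#'
#' @param frame non-negative preprocessed matrix.
#' @param params a [detect_params()] list.
#' @return List of class `mssef_result` with `f` (final response), `b`
#'   (final 0/1 mask) and `iterations` (per-scale `sigma`, `mu`, `sd` and
#'   threshold `T`).
#' @export
mssef <- function(frame, params = detect_params()) {
  stopifnot(is.matrix(frame))
  b <- matrix(1, nrow(frame), ncol(frame))
  iters <- vector("list", length(params$sigmas))
  f <- NULL
  for (k in seq_along(params$sigmas)) {
    kern <- log_kernel(params$sigmas[k])
    f <- EBImage::filter2(b * frame, kern, boundary = "replicate")
    f <- matrix(as.numeric(f), nrow(frame), ncol(frame))
    mu <- mean(f); s <- stats::sd(f)
    Tk <- mu + params$c * s
    b <- (f > Tk) * 1
    # a numerically constant response (e.g. a constant frame) has no spots
    if (diff(range(f)) < 1e-9 * max(1, max(abs(frame)))) b[] <- 0
    iters[[k]] <- list(sigma = params$sigmas[k], mu = mu, sd = s, T = Tk)
  }
  structure(list(f = f, b = b, iterations = iters), class = "mssef_result")
}

#' Extract candidate spots from an MSSEF result
#'
#' Candidates are local maxima of the final response inside the final mask
#' (3 x 3 neighborhood); peaks closer than `min_peak_sep_px` are merged
#' keeping the higher response.
#'
#' @param result an [mssef()] result.
#' @param min_peak_sep_px merge radius (px).
#' @return Data frame with integer `x`, `y` (0-based pixel position of the
#'   peak) and `response`, ordered by decreasing response.
#' @export
find_candidates <- function(result, min_peak_sep_px = 3) {
  f <- result$f; b <- result$b
  h <- nrow(f); w <- ncol(f)
  if (!any(b > 0)) return(data.frame(x = integer(0), y = integer(0),
                                     response = numeric(0)))
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- f
  ismax <- matrix(TRUE, h, w)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    ismax <- ismax & (f >= pad[(1 + di):(h + di), (1 + dj):(w + dj)])
  }
  idx <- which(ismax & b > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = integer(0), y = integer(0),
                                        response = numeric(0)))
  ord <- order(-f[idx])
  cx <- idx[ord, 2] - 1L
  cy <- idx[ord, 1] - 1L
  resp <- f[idx][ord]
  n <- length(cx)
  keep <- logical(n)
  kx <- numeric(n); ky <- numeric(n); nk <- 0L
  sep2 <- min_peak_sep_px^2
  for (i in seq_len(n)) {
    if (nk == 0L ||
        min((kx[seq_len(nk)] - cx[i])^2 + (ky[seq_len(nk)] - cy[i])^2) >= sep2) {
      keep[i] <- TRUE
      nk <- nk + 1L
      kx[nk] <- cx[i]; ky[nk] <- cy[i]
    }
  }
  data.frame(x = cx[keep], y = cy[keep], response = resp[keep])
}

#' Extract a classifier ROI around a candidate
#'
#' Returns the `roi_px x roi_px` patch whose pixel `(roi_px/2, roi_px/2)`
#' is the candidate position. Candidates closer than `roi_px / 2` to any
#' border are rejected (returned as `NULL`): both the classifier and the
#' centroid refinement need complete windows.
#'
#' @param frame numeric matrix.
#' @param x,y candidate position, 0-based integer pixels.
#' @param roi_px even patch edge.
#' @return Numeric `roi_px x roi_px` matrix, or `NULL` when the candidate
#'   is too close to a border.
#' @export
extract_roi <- function(frame, x, y, roi_px = 16) {
  if (roi_px %% 2 != 0) stop("roi_px must be even")
  half <- roi_px / 2
  h <- nrow(frame); w <- ncol(frame)
  if (x < half || x > w - half - 1 || y < half || y > h - half - 1)
    return(NULL)
  frame[(y - half + 1):(y + half), (x - half + 1):(x + half)]
}

#' Iterative center-of-mass subpixel refinement
#'
#' Starting from an integer candidate, repeatedly takes the window of
#' radius `refine_radius_px` around the current estimate, subtracts the
#' window minimum, and moves the estimate to the intensity centroid; stops
#' when the step falls below 0.01 px or after `refine_iters` iterations.
#'
#' @param frame numeric matrix (typically the background-subtracted frame).
#' @param x,y starting position (0-based pixels).
#' @param refine_radius_px window radius (px).
#' @param refine_iters iteration cap.
#' @return List with subpixel `x`, `y`, the number of iterations used and
#'   `degenerate` (`TRUE` when an all-constant window stopped refinement).
#' @export
refine_subpixel <- function(frame, x, y, refine_radius_px = 3,
                            refine_iters = 20) {
  h <- nrow(frame); w <- ncol(frame)
  r <- refine_radius_px
  cx <- x; cy <- y
  degenerate <- FALSE
  used <- 0
  for (it in seq_len(refine_iters)) {
    used <- it
    ix <- round(cx); iy <- round(cy)
    rows <- max(1, iy - r + 1):min(h, iy + r + 1)
    cols <- max(1, ix - r + 1):min(w, ix + r + 1)
    win <- frame[rows, cols, drop = FALSE]
    win <- win - min(win)
    s <- sum(win)
    if (s <= 0) { degenerate <- TRUE; break }
    xs <- cols - 1; ys <- rows - 1
    nx <- sum(colSums(win) * xs) / s
    ny <- sum(rowSums(win) * ys) / s
    step <- sqrt((nx - cx)^2 + (ny - cy)^2)
    # limit each move to the window radius
    if (step > r) {
      nx <- cx + (nx - cx) * r / step
      ny <- cy + (ny - cy) * r / step
    }
    cx <- nx; cy <- ny
    if (step < 0.01) break
  }
  list(x = cx, y = cy, iterations = used, degenerate = degenerate)
}

#' Detect particles in every frame of a sequence
#'
#' Runs the full detection cascade per frame: temporal background
#' subtraction and contrast equalization, multiscale spot enhancement,
#' local-maximum candidate extraction, classifier pruning at `p_min`, and
#' center-of-mass subpixel refinement. ROI mean brightness is measured on
#' the raw frames so downstream intensity evidence is in camera counts.
#'
#' @param seq an [image_sequence].
#' @param model a trained [train_classifier()] model, or `NULL` to accept
#'   all candidates (classifier bypass, mainly for diagnostics).
#' @param params a [detect_params()] list.
#' @param config full pipeline configuration (preprocessing group is used).
#' @param verbose print per-frame candidate/accepted counts.
#' @return List with `detections` (data frame: `frame`, `x`, `y`, `p_spot`,
#'   `roi_mean`) and `counts` (per-frame candidates and accepted counts).
#' @export
detect_sequence <- function(seq, model, params = detect_params(),
                            config = default_config(), verbose = FALSE) {
  stopifnot(inherits(seq, "image_sequence"))
  T <- n_frames(seq)
  pp <- config$preprocess
  work <- subtract_background(seq, m = min(pp$m, T), stat = pp$background_stat)
  half <- params$roi_px / 2
  det <- vector("list", T)
  counts <- data.frame(frame = 0:(T - 1), candidates = 0L, accepted = 0L)
  for (t in seq_len(T)) {
    bg_frame <- work$frames[, , t]
    frame <- equalize(bg_frame, clip = pp$clahe_clip, tile_px = pp$clahe_tile_px)
    res <- mssef(frame, params)
    cand <- find_candidates(res, params$min_peak_sep_px)
    counts$candidates[t] <- nrow(cand)
    if (nrow(cand) == 0) next
    h <- nrow(frame); w <- ncol(frame)
    ok <- cand$x >= half & cand$x <= w - half - 1 &
      cand$y >= half & cand$y <= h - half - 1
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    # gather all ROIs in one indexing operation (column-major pixel order)
    offs <- as.vector(outer(0:(params$roi_px - 1L),
                            (0:(params$roi_px - 1L)) * h, "+"))
    tl <- (cand$x - half) * h + (cand$y - half) + 1L   # top-left linear index
    pm <- matrix(frame[outer(tl, offs, "+")], nrow(cand), params$roi_px^2)
    p_spot <- if (is.null(model)) rep(1, nrow(cand)) else
      classify_patches(model, pm)[, 2]
    acc <- p_spot >= params$p_min
    cand <- cand[acc, , drop = FALSE]
    p_spot <- p_spot[acc]
    counts$accepted[t] <- nrow(cand)
    if (nrow(cand) == 0) next
    raw <- seq$frames[, , t]
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      ref <- refine_subpixel(bg_frame, cand$x[i], cand$y[i],
                             params$refine_radius_px, params$refine_iters)
      roi_raw <- extract_roi(raw, cand$x[i], cand$y[i], params$roi_px)
      data.frame(frame = t - 1L, x = ref$x, y = ref$y, p_spot = p_spot[i],
                 roi_mean = if (is.null(roi_raw)) NA_real_ else mean(roi_raw))
    })
    det[[t]] <- do.call(rbind, rows)
    if (verbose)
      message(sprintf("frame %d: %d candidates, %d accepted",
                      t - 1L, counts$candidates[t], counts$accepted[t]))
  }
  dets <- do.call(rbind, det[!vapply(det, is.null, logical(1))])
  if (is.null(dets))
    dets <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                       p_spot = numeric(0), roi_mean = numeric(0))
  rownames(dets) <- NULL
  list(detections = dets, counts = counts)
}
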