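#' Sliding-window temporal background subtraction
#'
#' For frame `i` the background is the per-pixel mean (or median) over the
#' window of `m` consecutive frames centered on `i`, truncated at the
#' sequence ends; the background is subtracted and negative values clipped
#' to zero. A centered window gives a symmetric estimate for particles
#' moving in either temporal direction.
#'
#' @param seq an [image_sequence].
#' @param m window length in frames, `1 <= m <= T`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A new [image_sequence] with floating-valued frames.
#' @export
subtract_background <- function(seq, m = 20, stat = c("mean", "median")) {
  stopifnot(inherits(seq, "image_sequence"))
  stat <- match.arg(stat)
  T <- n_frames(seq)
  if (m < 1 || m > T) stop("m must satisfy 1 <= m <= T")
  d <- dim(seq$frames)
  out <- array(0, d)
  half_lo <- floor((m - 1) / 2)
  half_hi <- m - 1 - half_lo
  flat <- matrix(seq$frames, d[1] * d[2], d[3])
  if (stat == "mean") {
    cs <- cbind(0, t(apply(flat, 1, cumsum)))
  }
  for (t in seq_len(T)) {
    lo <- max(1, t - half_lo)
    hi <- min(T, t + half_hi)
    bg <- if (stat == "mean") {
      (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
    } else {
      apply(flat[, lo:hi, drop = FALSE], 1, stats::median)
    }
    out[, , t] <- pmax(matrix(flat[, t] - bg, d[1], d[2]), 0)
  }
  res <- seq
  res$frames <- out
  res
}

#' Contrast-limited adaptive histogram equalization of one frame
#'
#' The frame is min-max normalized to `[0, 1]` and equalized tile-wise with
#' a clipped histogram (CLAHE). Because of the initial normalization two
#' frames identical up to a global affine intensity map produce identical
#' outputs. A constant frame is returned as an all-zero frame.
#'
#' @param frame non-negative numeric matrix.
#' @param clip clip limit as the fraction of the tile histogram a single bin
#'   may hold (default 0.01).
#' @param tile_px tile edge in pixels (default 32); must not exceed the
#'   frame size.
#' @return Matrix with values in `[0, 1]`.
#' @export
equalize <- function(frame, clip = 0.01, tile_px = 32) {
  stopifnot(is.matrix(frame))
  if (any(frame < 0)) stop("frame must be non-negative")
  if (tile_px > min(dim(frame))) stop("tile_px larger than frame")
  rng <- range(frame)
  if (rng[2] == rng[1]) return(matrix(0, nrow(frame), ncol(frame)))
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  ny <- max(2, round(nrow(frame) / tile_px))
  nx <- max(2, round(ncol(frame) / tile_px))
  out <- EBImage::clahe(norm, nx = nx, ny = ny, bins = 256,
                        limit = max(1, clip * 256))
  matrix(pmin(pmax(as.numeric(out), 0), 1), nrow(frame), ncol(frame))
}

# Shannon mutual information between two frames from a joint histogram.
mutual_information <- function(a, b, bins = 32) {
  ra <- range(a); rb <- range(b)
  if (ra[2] == ra[1] || rb[2] == rb[1]) return(0)
  ia <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * bins), bins - 1)
  ib <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * bins), bins - 1)
  jm <- matrix(tabulate(ia * bins + ib + 1, nbins = bins * bins) / length(a),
               bins, bins)               # rows index b's bin, columns a's
  pb <- rowSums(jm); pa <- colSums(jm)
  pm <- outer(pb, pa)
  nz <- jm > 0
  sum(jm[nz] * log(jm[nz] / pm[nz]))
}

# Shift an image by (dx, dy) pixels (x = columns, y = rows) with bilinear
# interpolation; out-of-range samples take the edge value.
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  # output pixel (r, c) samples input at (r - dy, c - dx)
  rr <- seq_len(h) - dy
  cc <- seq_len(w) - dx
  r0 <- pmin(pmax(floor(rr), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(cc), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(rr - r0, 0), 1); fc <- pmin(pmax(cc - c0, 0), 1)
  i00 <- img[r0, c0, drop = FALSE]; i10 <- img[r1, c0, drop = FALSE]
  i01 <- img[r0, c1, drop = FALSE]; i11 <- img[r1, c1, drop = FALSE]
  wr <- matrix(fr, h, w); wc <- matrix(fc, h, w, byrow = TRUE)
  i00 * (1 - wr) * (1 - wc) + i10 * wr * (1 - wc) +
    i01 * (1 - wr) * wc + i11 * wr * wc
}

# Translation between two frames maximizing mutual information: coarse
# integer grid search of +/- max_shift px followed by parabolic refinement.
register_pair <- function(ref, mov, max_shift = 5) {
  shifts <- -max_shift:max_shift
  mi <- matrix(NA_real_, length(shifts), length(shifts))
  crop <- max_shift + 1
  h <- nrow(ref); w <- ncol(ref)
  rr <- crop:(h - crop); cc <- crop:(w - crop)
  refc <- ref[rr, cc]
  for (i in seq_along(shifts)) for (j in seq_along(shifts)) {
    movc <- mov[rr + shifts[i], cc + shifts[j]]
    mi[i, j] <- mutual_information(refc, movc)
  }
  best <- which(mi == max(mi), arr.ind = TRUE)[1, ]
  refine <- function(idx, axis_vals, slice) {
    if (idx == 1 || idx == length(axis_vals)) return(axis_vals[idx])
    y0 <- slice[idx - 1]; y1 <- slice[idx]; y2 <- slice[idx + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) return(axis_vals[idx])
    axis_vals[idx] + 0.5 * (y0 - y2) / den
  }
  dy <- refine(best[1], shifts, mi[, best[2]])
  dx <- refine(best[2], shifts, mi[best[1], ])
  # mov[r + dy, c + dx] aligns with ref[r, c]: mov is shifted by (-dx, -dy)
  c(dx = -dx, dy = -dy)
}

#' Register an image sequence by translation
#'
#' Estimates a 2D translation per frame that maximizes mutual information
#' against the previous registered frame (32-bin joint histogram, integer
#' grid search of +/- `max_shift` px with parabolic sub-pixel refinement)
#' and applies the cumulative shift by bilinear interpolation. Intended for
#' slow rigid drift of the specimen; it is idempotent within a fraction of
#' a pixel.
#'
#' @param seq an [image_sequence] with `T >= 2`.
#' @param max_shift largest per-frame shift searched (px).
#' @return List with `sequence` (registered [image_sequence]) and `shifts`
#'   (T x 2 matrix of applied cumulative `(dx, dy)` per frame; row 1 is
#'   zero).
#' @export
register_sequence <- function(seq, max_shift = 5) {
  stopifnot(inherits(seq, "image_sequence"))
  T <- n_frames(seq)
  if (T < 2) stop("registration needs at least 2 frames")
  out <- seq$frames
  shifts <- matrix(0, T, 2, dimnames = list(NULL, c("dx", "dy")))
  for (t in 2:T) {
    s <- tryCatch(register_pair(out[, , t - 1], seq$frames[, , t], max_shift),
                  error = function(e) {
                    warning("registration failed at frame ", t - 1,
                            "; keeping identity shift")
                    c(dx = 0, dy = 0)
                  })
    shifts[t, ] <- s
    out[, , t] <- if (all(s == 0)) seq$frames[, , t] else
      shift_image(seq$frames[, , t], s[1], s[2])
  }
  res <- seq
  res$frames <- out
  list(sequence = res, shifts = shifts)
}
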