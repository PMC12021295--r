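#' Scenario parameters for the synthetic movie generator
#'
#' Describes a simulated time-lapse of sub-resolution moving spots over a
#' diffuse Poisson background with bright immobile distractor blobs, the
#' validation scenario used throughout the package: spots at three density
#' levels and Poisson-noise SNRs of 1, 2, 4 and 7.
#'
#' @param T frame count (>= 2).
#' @param H,W frame size in pixels.
#' @param n_particles number of moving spots; when `NULL` it is derived from
#'   `density`.
#' @param density `"low"`, `"middle"` or `"high"`: 10 / 50 / 100 particles
#'   per 512 x 512 frame, scaled by area.
#' @param snr peak signal-to-noise ratio of the Poisson model, defined as
#'   `A / sqrt(A + b)` for spot peak amplitude `A` above background `b`
#'   (shot noise at the peak); any positive value, typically 1, 2, 4 or 7.
#' @param psf_sigma_px Gaussian spot width (px).
#' @param motion one of `"directed"`, `"brownian"`, `"switching"`, or a list
#'   with fields `model` plus `speed_px` / `heading_deg` (directed; heading
#'   follows the display convention, 0 = +x, 90 = up i.e. decreasing row),
#'   `step_sd_px` (brownian), or `speed_px`, `step_sd_px`,
#'   `mean_moving_frames`, `mean_paused_frames` (switching).
#' @param n_distractors immobile Golgi-like blobs: 2D Gaussians with
#'   `sigma` in `[3, 6]` px and 3-10x the spot amplitude.
#' @param background_level mean background counts `b`.
#' @param seed integer RNG seed; identical parameters and seed give
#'   byte-identical output.
#' @return Named list of validated parameters.
#' @export
scenario_params <- function(T = 100L, H = 512L, W = 512L,
                            n_particles = NULL, density = "low",
                            snr = 7, psf_sigma_px = 1.3,
                            motion = "switching",
                            n_distractors = 10L, background_level = 50,
                            seed = 1L) {
  if (T < 2) stop("T must be >= 2")
  if (snr <= 0) stop("snr must be positive")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  if (is.null(n_particles)) {
    if (is.null(H) || is.null(W))
      stop("density preset requires H and W")
    per512 <- c(low = 10, middle = 50, high = 100)[[match.arg(density, c("low", "middle", "high"))]]
    n_particles <- max(1L, round(per512 * (H * W) / 512^2))
  }
  if (is.character(motion)) {
    motion <- switch(match.arg(motion, c("directed", "brownian", "switching")),
      directed  = list(model = "directed", speed_px = 2, heading_deg = NULL),
      brownian  = list(model = "brownian", step_sd_px = 0.5),
      switching = list(model = "switching", speed_px = 2, step_sd_px = 0.15,
                       mean_moving_frames = 10, mean_paused_frames = 5))
  }
  list(T = as.integer(T), H = as.integer(H), W = as.integer(W),
       n_particles = as.integer(n_particles), snr = snr,
       psf_sigma_px = psf_sigma_px, motion = motion,
       n_distractors = as.integer(n_distractors),
       background_level = background_level, seed = as.integer(seed))
}

#' Spot peak amplitude for a requested Poisson SNR
#'
#' Inverts `snr = A / sqrt(A + b)` for the peak amplitude `A` above
#' background `b`.
#'
#' @param snr requested peak SNR (> 0).
#' @param background mean background counts `b`.
#' @return Peak amplitude `A` in counts.
#' @export
snr_amplitude <- function(snr, background) {
  (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
}

# Add an isotropic Gaussian of amplitude `amp`, width `sigma`, centered at
# subpixel (x0, y0), into matrix `img` (in place semantics via return).
add_gaussian <- function(img, x0, y0, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  rows <- max(1, floor(y0 + 1 - r)):min(h, ceiling(y0 + 1 + r))
  cols <- max(1, floor(x0 + 1 - r)):min(w, ceiling(x0 + 1 + r))
  if (!length(rows) || !length(cols)) return(img)
  dy <- (rows - 1) - y0
  dx <- (cols - 1) - x0
  g <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * g
  img
}

# Reflect a coordinate into [lo, hi].
reflect1 <- function(p, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(p)))
  q <- (p - lo) %% (2 * span)
  q <- ifelse(q > span, 2 * span - q, q)
  q + lo
}

# Simulate particle center trajectories; returns list(x = T x n, y = T x n,
# moving = T x n logical). Particles reflect at a soft margin so they stay
# in the usable field of view.
simulate_motion <- function(params) {
  T <- params$T; n <- params$n_particles
  H <- params$H; W <- params$W
  margin <- 12
  if (W <= 2 * margin || H <= 2 * margin) margin <- 2
  mo <- params$motion
  x <- matrix(0, T, n); y <- matrix(0, T, n); moving <- matrix(TRUE, T, n)
  x[1, ] <- runif(n, margin, W - 1 - margin)
  y[1, ] <- runif(n, margin, H - 1 - margin)
  speed <- if (!is.null(mo$speed_px)) mo$speed_px else 0
  if (identical(mo$model, "directed") && speed * 2 > min(W, H) - 2 * margin)
    stop("particle speed would exit the frame in < 2 frames")
  heading <- if (!is.null(mo$heading_deg)) rep(mo$heading_deg, n) else runif(n, 0, 360)
  hrad <- heading * pi / 180
  vx <- speed * cos(hrad); vy <- -speed * sin(hrad)
  if (identical(mo$model, "switching")) {
    # geometric dwell times; start each particle in a random phase
    state <- runif(n) < mo$mean_moving_frames /
      (mo$mean_moving_frames + mo$mean_paused_frames)
    dwell <- ifelse(state, rgeom(n, 1 / mo$mean_moving_frames),
                    rgeom(n, 1 / mo$mean_paused_frames)) + 1
  }
  for (t in 2:T) {
    if (identical(mo$model, "directed")) {
      x[t, ] <- x[t - 1, ] + vx
      y[t, ] <- y[t - 1, ] + vy
    } else if (identical(mo$model, "brownian")) {
      x[t, ] <- x[t - 1, ] + rnorm(n, 0, mo$step_sd_px)
      y[t, ] <- y[t - 1, ] + rnorm(n, 0, mo$step_sd_px)
      moving[t, ] <- FALSE
    } else if (identical(mo$model, "switching")) {
      jx <- rnorm(n, 0, mo$step_sd_px); jy <- rnorm(n, 0, mo$step_sd_px)
      x[t, ] <- x[t - 1, ] + ifelse(state, vx, 0) + jx
      y[t, ] <- y[t - 1, ] + ifelse(state, vy, 0) + jy
      moving[t, ] <- state
      dwell <- dwell - 1
      flip <- dwell <= 0
      if (any(flip)) {
        state[flip] <- !state[flip]
        dwell[flip] <- ifelse(state[flip],
                              rgeom(sum(flip), 1 / mo$mean_moving_frames),
                              rgeom(sum(flip), 1 / mo$mean_paused_frames)) + 1
        # a reversal of heading on re-start keeps switching tracks wandering
        turn <- runif(sum(flip), 0, 2 * pi)
        vx[flip] <- speed * cos(turn); vy[flip] <- speed * sin(turn)
      }
    } else stop("unknown motion model '", mo$model, "'")
    # reflect into the soft margin, mirroring the velocity component
    ox <- x[t, ]; oy <- y[t, ]
    x[t, ] <- reflect1(x[t, ], margin, W - 1 - margin)
    y[t, ] <- reflect1(y[t, ], margin, H - 1 - margin)
    if (identical(mo$model, "directed") || identical(mo$model, "switching")) {
      vx[ox != x[t, ]] <- -vx[ox != x[t, ]]
      vy[oy != y[t, ]] <- -vy[oy != y[t, ]]
    }
  }
  moving[1, ] <- moving[min(2, T), ]
  list(x = x, y = y, moving = moving)
}

#' Simulate an image sequence with ground-truth tracks
#'
#' Particles are rendered as isotropic Gaussian spots of amplitude
#' `snr_amplitude(snr, background_level)` on a flat background; distractor
#' blobs are brighter, wider (>= 3x the spot width) and immobile; per-pixel
#' Poisson noise is then drawn so the expected image equals the noiseless
#' render. Ground-truth positions are the noiseless spot centers.
#'
#' @param params a [scenario_params()] list.
#' @param pixel_size_nm,frame_interval_s metadata attached to the output
#'   (defaults: 100 nm pixels at 4 frames per second, typical of fast
#'   Airyscan vesicle imaging).
#' @return List with `sequence` (an [image_sequence]), `ground_truth` (a
#'   [track_set] with one track per particle), `moving` (T x n logical
#'   matrix of per-frame motion labels) and `distractors` (data frame of
#'   blob centers, widths and amplitudes).
#' @export
simulate_movie <- function(params, pixel_size_nm = 100, frame_interval_s = 0.25) {
  set.seed(params$seed)
  T <- params$T; H <- params$H; W <- params$W
  b <- params$background_level
  A <- snr_amplitude(params$snr, b)

  if (params$n_particles > 0) {
    mot <- simulate_motion(params)
  } else {
    mot <- list(x = matrix(0, T, 0), y = matrix(0, T, 0),
                moving = matrix(FALSE, T, 0))
  }
  nd <- params$n_distractors
  distractors <- data.frame(x = runif(nd, 0, W - 1), y = runif(nd, 0, H - 1),
                            sigma = runif(nd, 3, 6),
                            amp = A * runif(nd, 3, 10))

  base <- matrix(b, H, W)
  for (d in seq_len(nd))
    base <- add_gaussian(base, distractors$x[d], distractors$y[d],
                         distractors$amp[d], distractors$sigma[d])

  frames <- array(0, c(H, W, T))
  for (t in seq_len(T)) {
    img <- base
    for (p in seq_len(params$n_particles))
      img <- add_gaussian(img, mot$x[t, p], mot$y[t, p], A, params$psf_sigma_px)
    noisy <- rpois(length(img), as.vector(img))
    frames[, , t] <- matrix(pmin(noisy, 65535), H, W)
  }

  gt <- track_set(lapply(seq_len(params$n_particles), function(p) {
    new_track(id = p, frames = 0:(T - 1), x = mot$x[, p], y = mot$y[, p])
  }), source = "synthetic ground truth",
  pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s)

  list(sequence = image_sequence(frames, pixel_size_nm, frame_interval_s,
                                 bit_depth = 16L),
       ground_truth = gt, moving = mot$moving, distractors = distractors)
}

#' Render labeled training patches from a synthetic scenario
#'
#' Positive patches are centered (with +/- 1 px jitter) on rendered spots;
#' negative patches are drawn from diffuse background, distractor interiors
#' and distractor edges, so the classifier learns to reject exactly the
#' nuisance structure the generator produces. Patches are cut from frames
#' processed the same way detection processes them (background subtraction
#' and contrast equalization) when `preprocess = TRUE`.
#'
#' @param params a [scenario_params()] list.
#' @param n_pos,n_neg patch counts per class.
#' @param roi_px even patch edge, >= 8.
#' @param preprocess cut patches from preprocessed frames (default) rather
#'   than raw ones.
#' @param config pipeline configuration for the preprocessing step.
#' @return List with `patches` (matrix, one row per patch, `roi_px^2`
#'   columns, column-major pixel order), `labels` (1 = spot, 0 = background)
#'   and `roi_px`.
#' @export
render_training_patches <- function(params, n_pos = 200, n_neg = 200,
                                    roi_px = 16, preprocess = TRUE,
                                    config = default_config()) {
  if (roi_px %% 2 != 0 || roi_px < 8) stop("roi_px must be even and >= 8")
  sim <- simulate_movie(params)
  set.seed(params$seed + 1L)
  seq <- sim$sequence
  if (preprocess) {
    seq <- subtract_background(seq, m = min(config$preprocess$m, n_frames(seq)),
                               stat = config$preprocess$background_stat)
    for (t in seq_len(n_frames(seq)))
      seq$frames[, , t] <- equalize(seq$frames[, , t],
                                    clip = config$preprocess$clahe_clip,
                                    tile_px = config$preprocess$clahe_tile_px)
  }
  H <- params$H; W <- params$W; T <- params$T
  half <- roi_px / 2

  gt <- sim$ground_truth
  pos_pool <- do.call(rbind, lapply(gt$tracks, function(tr)
    cbind(frame = tr$det$frame, x = tr$det$x, y = tr$det$y)))
  if (is.null(pos_pool)) pos_pool <- matrix(0, 0, 3)
  inside <- pos_pool[, "x"] >= half & pos_pool[, "x"] < W - half &
    pos_pool[, "y"] >= half & pos_pool[, "y"] < H - half
  pos_pool <- pos_pool[inside, , drop = FALSE]
  if (nrow(pos_pool) < n_pos)
    stop("scenario cannot supply ", n_pos, " positive patches without duplicates")
  pick <- sample(nrow(pos_pool), n_pos)

  cut_patch <- function(frame, cx, cy) {
    cx <- round(cx); cy <- round(cy)
    rows <- (cy - half + 1):(cy + half)
    cols <- (cx - half + 1):(cx + half)
    as.vector(seq$frames[rows, cols, frame + 1L])
  }

  pats <- matrix(0, n_pos + n_neg, roi_px^2)
  for (i in seq_len(n_pos)) {
    j <- pick[i]
    cx <- pos_pool[j, "x"] + sample(-1:1, 1)
    cy <- pos_pool[j, "y"] + sample(-1:1, 1)
    cx <- min(max(cx, half), W - half - 1)
    cy <- min(max(cy, half), H - half - 1)
    pats[i, ] <- cut_patch(pos_pool[j, "frame"], cx, cy)
  }

  # negatives: background away from spots, distractor centers, distractor rims
  dis <- sim$distractors
  neg_centers <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(neg_centers) < n_neg && tries < 200 * n_neg) {
    tries <- tries + 1
    t0 <- sample(T, 1) - 1L
    kind <- if (nrow(dis) > 0) sample(c("bg", "core", "rim"), 1,
                                      prob = c(0.5, 0.25, 0.25)) else "bg"
    if (kind == "bg") {
      cx <- runif(1, half, W - half - 1); cy <- runif(1, half, H - half - 1)
    } else {
      d <- sample(nrow(dis), 1)
      off <- if (kind == "core") 0 else dis$sigma[d] * 1.5
      ang <- runif(1, 0, 2 * pi)
      cx <- dis$x[d] + off * cos(ang); cy <- dis$y[d] + off * sin(ang)
      if (cx < half || cx >= W - half || cy < half || cy >= H - half) next
    }
    # reject centers that sit on a true particle
    if (params$n_particles > 0) {
      px <- sim$ground_truth$tracks
      dd <- vapply(px, function(tr)
        min((tr$det$x[t0 + 1] - cx)^2 + (tr$det$y[t0 + 1] - cy)^2), numeric(1))
      if (min(dd) < (2 * params$psf_sigma_px + 1)^2) next
    }
    neg_centers <- rbind(neg_centers, c(t0, cx, cy))
  }
  if (nrow(neg_centers) < n_neg)
    stop("scenario cannot supply ", n_neg, " negative patches")
  for (i in seq_len(n_neg))
    pats[n_pos + i, ] <- cut_patch(neg_centers[i, 1], neg_centers[i, 2],
                                   neg_centers[i, 3])

  list(patches = pats,
       labels = c(rep(1L, n_pos), rep(0L, n_neg)),
       roi_px = as.integer(roi_px))
}
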