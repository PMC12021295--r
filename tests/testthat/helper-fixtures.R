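# Shared fixtures. Heavy objects (trained classifier, full evaluation runs)
# are built once per test session and memoized, so several test files can
# reuse them without retraining or re-simulating.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# the standard evaluation imaging conditions: 512 x 512, low density,
# immobile Golgi-like distractors, 100 nm pixels at 4 fps
fx_eval_params <- function(snr = 7, T = 100, seed = 11) {
  scenario_params(T = T, H = 512, W = 512, density = "low", snr = snr,
                  n_distractors = 10, seed = seed)
}

# classifier trained on a scenario with the same imaging conditions
fx_model <- function() {
  fx_memo("model", function() {
    par <- fx_eval_params(T = 30, seed = 5)
    tp <- render_training_patches(par, n_pos = 250, n_neg = 250)
    train_classifier(tp$patches, tp$labels, epochs = 15, seed = 0)
  })
}

# held-out patch sets (different seed than fx_model's training scenario)
fx_holdout_patches <- function() {
  fx_memo("holdout", function() {
    par <- fx_eval_params(T = 30, seed = 21)
    render_training_patches(par, n_pos = 60, n_neg = 60)
  })
}

# full pipeline run at one SNR of the evaluation scenario
fx_eval_run <- function(snr) {
  fx_memo(paste0("run_snr", snr), function() {
    sim <- simulate_movie(fx_eval_params(snr = snr))
    det <- detect_sequence(sim$sequence, fx_model())
    lp <- link_params()
    tracklets <- form_tracklets(det$detections, lp)
    tracks <- multi_pass_link(tracklets, lp)
    filtered <- filter_tracks(tracks, min_points = 3)
    est <- track_set(filtered, pixel_size_nm = 100, frame_interval_s = 0.25)
    pairing <- pair_tracks(sim$ground_truth, est)
    report <- compute_metrics(sim$ground_truth, est, pairing)
    list(sim = sim, detections = det$detections, est = est,
         report = report)
  })
}

# per-point detection recall (fraction of ground-truth positions with an
# accepted detection within `radius` px in the same frame) and the mean
# absolute localization error of those matches
fx_detection_recall <- function(sim, detections, radius = 2) {
  tot <- 0L; hit <- 0L; err <- numeric(0)
  for (tr in sim$ground_truth$tracks) {
    for (i in seq_len(nrow(tr$det))) {
      f <- tr$det$frame[i]
      tot <- tot + 1L
      df <- detections[detections$frame == f, , drop = FALSE]
      if (nrow(df) == 0) next
      d <- sqrt((df$x - tr$det$x[i])^2 + (df$y - tr$det$y[i])^2)
      if (min(d) <= radius) {
        hit <- hit + 1L
        err <- c(err, min(d))
      }
    }
  }
  list(recall = hit / tot, mae = mean(err))
}

# straight synthetic track: `n` points from (x0, y0) stepping (dx, dy) per
# frame
fx_line_track <- function(n, dx = 1, dy = 0, x0 = 0, y0 = 0, id = 1,
                          frames = NULL, brightness = NULL) {
  if (is.null(frames)) frames <- 0:(n - 1)
  new_track(id, frames, x0 + dx * seq(0, n - 1), y0 + dy * seq(0, n - 1),
            brightness = brightness)
}

# random wandering track for property tests
fx_random_track <- function(n, id = 1) {
  new_track(id, 0:(n - 1), cumsum(rnorm(n, 0, 2)) + 50,
            cumsum(rnorm(n, 0, 2)) + 50,
            brightness = runif(n, 50, 150))
}

# brute-force oracle for the gated assignment problem: enumerate every
# partial injection rows -> columns, maximize cardinality then minimize cost
fx_brute_assignment <- function(costs, gate = Inf) {
  nr <- nrow(costs); nc <- ncol(costs)
  best <- list(card = -1L, cost = Inf)
  rec <- function(i, used, card, cost) {
    if (i > nr) {
      if (card > best$card ||
          (card == best$card && cost < best$cost))
        best <<- list(card = card, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used, card, cost)
    for (j in which(!used)) {
      if (costs[i, j] <= gate) {
        used[j] <- TRUE
        rec(i + 1L, used, card + 1L, cost + costs[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nc), 0L, 0)
  best
}

# render an isotropic Gaussian spot analytically (independent of the
# generator internals)
fx_render_spot <- function(h, w, x0, y0, amp, sigma, background = 0) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  background + amp * exp(-outer((ys - y0)^2, (xs - x0)^2, "+") / (2 * sigma^2))
}
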