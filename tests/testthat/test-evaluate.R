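ts_of <- function(...) track_set(list(...))

test_that("a perfect estimate scores 1 on every measure with zero RMSE", {
  set.seed(61)
  gt <- track_set(lapply(1:4, function(i) fx_random_track(8, id = i)))
  pairing <- pair_tracks(gt, gt)
  rep <- compute_metrics(gt, gt, pairing)
  expect_equal(rep$alpha, 1)
  expect_equal(rep$beta, 1)
  expect_equal(rep$jsc, 1)
  expect_equal(rep$jsc_theta, 1)
  expect_equal(rep$gamma, 1)
  expect_equal(rep$rmse_px, 0)
  expect_equal(sum(pairing$pairs$distance), 0)
})

test_that("spurious tracks lower beta and jsc_theta but not alpha", {
  set.seed(62)
  gt <- track_set(lapply(1:3, function(i) fx_random_track(8, id = i)))
  est_plus <- track_set(c(gt$tracks,
                          list(fx_line_track(6, x0 = 500, y0 = 500,
                                             id = "fake"))))
  base <- compute_metrics(gt, gt, pair_tracks(gt, gt))
  plus <- compute_metrics(gt, est_plus, pair_tracks(gt, est_plus))
  expect_equal(plus$alpha, base$alpha)
  expect_lt(plus$beta, base$beta)
  expect_lt(plus$jsc_theta, base$jsc_theta)
  expect_equal(plus$spurious_est_tracks, 1)
})

test_that("a constant 1 px offset gives RMSE 1 and the predicted alpha", {
  gt <- ts_of(fx_line_track(10, dx = 2, id = 1))
  off <- fx_line_track(10, dx = 2, x0 = 1, id = 1)   # shifted by (1, 0)
  est <- ts_of(off)
  rep <- compute_metrics(gt, est, pair_tracks(gt, est,
                                              pairing_params(epsilon_px = 5)))
  expect_equal(rep$rmse_px, 1)
  expect_equal(rep$alpha, 1 - 1 / 5)     # every frame contributes 1 of eps=5
  expect_equal(rep$gamma, 1)
})

test_that("an empty estimate scores zero", {
  gt <- ts_of(fx_line_track(6, id = 1))
  est <- track_set()
  rep <- compute_metrics(gt, est, pair_tracks(gt, est))
  expect_equal(rep$alpha, 0)
  expect_equal(rep$gamma, 0)
  expect_equal(rep$jsc, 0)
  expect_true(is.na(rep$rmse_px))
})

test_that("pairing separates copies, misses and fabrications", {
  set.seed(63)
  g1 <- fx_random_track(8, id = 1)
  g2 <- fx_random_track(8, id = 2)
  g2$det$x <- g2$det$x + 120          # disjoint region
  gt <- ts_of(g1, g2)
  est <- ts_of(new_track("copy", g1$det$frame, g1$det$x, g1$det$y),
               fx_line_track(5, x0 = 400, y0 = 400, id = "fab"))
  pairing <- pair_tracks(gt, est)
  expect_equal(nrow(pairing$pairs), 1)
  expect_equal(pairing$pairs$gt, 1)
  expect_equal(pairing$unpaired_gt, 2)
  expect_equal(pairing$spurious_est, 2)
})

test_that("empty ground truth is an error", {
  est <- ts_of(fx_line_track(5, id = 1))
  expect_error(compute_metrics(track_set(), est,
                               pair_tracks(track_set(), est)),
               "empty ground truth")
})

test_that("beta never exceeds alpha on random degraded estimates", {
  set.seed(64)
  for (i in 1:20) {
    gt <- track_set(lapply(1:4, function(k) fx_random_track(10, id = k)))
    est_tracks <- list()
    for (k in 1:4) {
      d <- gt$tracks[[k]]$det
      keep <- sort(sample(10, sample(3:10, 1)))
      est_tracks[[k]] <- new_track(k, d$frame[keep],
                                   d$x[keep] + rnorm(length(keep), 0, 2),
                                   d$y[keep] + rnorm(length(keep), 0, 2))
    }
    if (i %% 2 == 0)
      est_tracks <- c(est_tracks, list(fx_line_track(4, x0 = 300,
                                                     y0 = 300, id = 99)))
    est <- track_set(est_tracks)
    rep <- compute_metrics(gt, est, pair_tracks(gt, est))
    expect_gte(rep$alpha, 0); expect_lte(rep$alpha, 1)
    expect_gte(rep$beta, 0)
    expect_lte(rep$beta, rep$alpha + 1e-12)
  }
})

test_that("metrics are invariant to track order and joint translation", {
  set.seed(65)
  gt <- track_set(lapply(1:3, function(k) fx_random_track(8, id = k)))
  est_tracks <- lapply(gt$tracks, function(t)
    new_track(t$id, t$det$frame, t$det$x + rnorm(8), t$det$y + rnorm(8)))
  est <- track_set(est_tracks)
  r1 <- compute_metrics(gt, est, pair_tracks(gt, est))

  perm <- track_set(est_tracks[c(3, 1, 2)])
  r2 <- compute_metrics(gt, perm, pair_tracks(gt, perm))
  expect_equal(r1$alpha, r2$alpha)
  expect_equal(r1$rmse_px, r2$rmse_px)

  shift <- function(ts) track_set(lapply(ts$tracks, function(t)
    new_track(t$id, t$det$frame, t$det$x + 17, t$det$y - 9)))
  r3 <- compute_metrics(shift(gt), shift(est),
                        pair_tracks(shift(gt), shift(est)))
  expect_equal(r1$alpha, r3$alpha, tolerance = 1e-12)
  expect_equal(r1$jsc, r3$jsc)
})

test_that("deleting estimated points never improves alpha or jsc", {
  set.seed(66)
  gt <- track_set(lapply(1:3, function(k) fx_random_track(10, id = k)))
  est_full <- track_set(lapply(gt$tracks, function(t)
    new_track(t$id, t$det$frame, t$det$x + rnorm(10, 0, 1),
              t$det$y + rnorm(10, 0, 1))))
  r_full <- compute_metrics(gt, est_full, pair_tracks(gt, est_full))
  for (drop_n in c(2, 5, 8)) {
    est_cut <- track_set(lapply(est_full$tracks, function(t) {
      keep <- sort(sample(10, 10 - drop_n))
      new_track(t$id, t$det$frame[keep], t$det$x[keep], t$det$y[keep])
    }))
    r_cut <- compute_metrics(gt, est_cut, pair_tracks(gt, est_cut))
    expect_lte(r_cut$alpha, r_full$alpha + 1e-12)
    expect_lte(r_cut$jsc, r_full$jsc + 1e-12)
  }
})

test_that("evaluation reports round-trip through files", {
  set.seed(67)
  gt <- track_set(lapply(1:2, function(k) fx_random_track(6, id = k)),
                  pixel_size_nm = 100, frame_interval_s = 0.25)
  gt_path <- withr::local_tempfile(fileext = ".json")
  rep_path <- withr::local_tempfile(fileext = ".json")
  write_tracks(gt, gt_path)
  rep <- evaluate_run(gt_path, gt_path, report_path = rep_path)
  expect_equal(rep$alpha, 1)
  back <- jsonlite::fromJSON(rep_path)
  expect_equal(back$alpha, 1)
  expect_equal(back$gamma, 1)
  expect_equal(back$parameters$epsilon_px, 5)
})
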