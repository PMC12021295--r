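test_that("assignment handles the canonical small cases", {
  res <- solve_assignment(matrix(c(1, 5, 5, 1), 2, 2, byrow = TRUE))
  expect_equal(res$total_cost, 2)
  expect_equal(res$matches[order(res$matches[, 1]), "col"], c(1, 2),
               ignore_attr = TRUE)

  res <- solve_assignment(matrix(3, 1, 1), gate = 2)
  expect_equal(nrow(res$matches), 0)
  expect_equal(res$unmatched_rows, 1)
  expect_equal(res$unmatched_cols, 1)
})

test_that("assignment equals the brute-force optimum on random matrices", {
  set.seed(99)
  for (i in 1:25) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    costs <- matrix(round(runif(nr * nc, 0, 10), 2), nr, nc)
    gate <- if (i %% 3 == 0) 5 else Inf
    got <- solve_assignment(costs, gate)
    want <- fx_brute_assignment(costs, gate)
    expect_equal(nrow(got$matches), want$card)
    expect_equal(got$total_cost, want$cost, tolerance = 1e-9)
  }
})

test_that("tracklet formation follows the proximity contract", {
  lp <- link_params(max_link_dist_px = 2)
  det <- data.frame(frame = 0:2, x = 0:2, y = 0)
  tl <- form_tracklets(det, lp)
  expect_length(tl, 1)
  expect_equal(tl[[1]]$det$x, 0:2)

  # two parallel particles far apart never swap
  det2 <- data.frame(frame = rep(0:4, 2), x = c(0:4, 0:4),
                     y = rep(c(0, 10), each = 5))
  tl2 <- form_tracklets(det2, lp)
  expect_length(tl2, 2)
  expect_true(all(vapply(tl2, function(t) length(unique(t$det$y)) == 1,
                         logical(1))))

  # a gap within max_missed_frames keeps the tracklet alive
  det3 <- data.frame(frame = c(0, 2), x = c(0, 1), y = 0)
  tl3 <- form_tracklets(det3, link_params(max_link_dist_px = 2,
                                          max_missed_frames = 1))
  expect_length(tl3, 1)
  expect_equal(tl3[[1]]$det$frame, c(0L, 2L))

  # a jump beyond the gate starts a new tracklet
  det4 <- data.frame(frame = 0:1, x = c(0, 5), y = 0)
  expect_length(form_tracklets(det4, lp), 2)
})

test_that("tracklet length is capped with a continuing successor", {
  det <- data.frame(frame = 0:14, x = 0:14, y = 0)
  tl <- form_tracklets(det, link_params(max_link_dist_px = 2,
                                        max_tracklet_len = 5))
  expect_length(tl, 3)
  expect_equal(sort(vapply(tl, function(t) nrow(t$det), numeric(1))),
               c(5, 5, 5))
  all_frames <- sort(unlist(lapply(tl, function(t) t$det$frame)))
  expect_equal(all_frames, 0:14)
})

test_that("connectivity scores are probabilities and respect the gates", {
  a <- fx_line_track(5, dx = 2, brightness = rep(100, 5))
  b <- fx_line_track(5, dx = 2, x0 = 12, frames = 6:10,
                     brightness = rep(100, 5))
  lp <- link_params()
  sc <- score_pair(a, b, lp)
  expect_true(sc$p_c >= 0 && sc$p_c <= 1)
  net <- vestrack:::bn_build(lp$bn)
  post <- bn_infer(net, "CS",
                   sc$evidence[c("I", "Or", "Sp", "Od", "Ov", "G", "D")])
  expect_equal(sum(post), 1, tolerance = 1e-12)

  # spatial gate
  far <- fx_line_track(5, dx = 2, x0 = 200, frames = 6:10)
  expect_null(score_pair(a, far, lp))
  # temporal gate
  late <- fx_line_track(5, dx = 2, x0 = 12, frames = 20:24)
  expect_null(score_pair(a, late, lp))
})

test_that("enumeration inference agrees with the closed-form odds product", {
  lp <- link_params()
  a <- fx_line_track(5, dx = 2, brightness = rep(100, 5))
  b <- fx_line_track(5, dx = 2, x0 = 12, frames = 6:10,
                     brightness = rep(110, 5))
  sc <- score_pair(a, b, lp)
  ev <- sc$evidence
  bn <- lp$bn
  seq_state <- if (ev$Ov == "TRUE") "overlap" else
    if (ev$Od == "TRUE") "sequential" else "reversed"
  o <- bn$prior_true / (1 - bn$prior_true) *
    bn$odds$intensity[[ev$I]] * bn$odds$orientation[[ev$Or]] *
    bn$odds$speed[[ev$Sp]] * bn$odds$sequence[[seq_state]] *
    bn$odds$gap[[ev$G]] * bn$odds$distance[[ev$D]]
  expect_equal(sc$p_c, o / (1 + o), tolerance = 1e-12)
})

test_that("aligned continuations outscore reversed and overlapping ones", {
  lp <- link_params()
  a <- new_track(1, 0:4, seq(0, 8, by = 2), rep(0, 5),
                 brightness = rep(100, 5))
  aligned <- new_track(2, 6:10, seq(12, 20, by = 2), rep(0, 5),
                       brightness = rep(100, 5))
  reversed <- new_track(3, 6:10, seq(12, 4, by = -2), rep(0, 5),
                        brightness = rep(100, 5))
  p_al <- score_pair(a, aligned, lp)$p_c
  p_rev <- score_pair(a, reversed, lp)$p_c
  expect_gt(p_al, p_rev)

  # same geometry, shifted one frame earlier so the pair overlaps in time
  no_ov <- new_track(4, 5:9, seq(10, 18, by = 2), rep(0, 5),
                     brightness = rep(100, 5))
  ov <- new_track(5, 4:8, seq(10, 18, by = 2), rep(0, 5),
                  brightness = rep(100, 5))
  expect_lte(score_pair(a, ov, lp)$p_c, score_pair(a, no_ov, lp)$p_c)
})

test_that("a trajectory split by a detection gap is relinked into one track", {
  det <- data.frame(frame = c(0:4, 7:11), x = c(0:4, 7:11) * 2, y = 0,
                    roi_mean = 100)
  lp <- link_params()
  tl <- form_tracklets(det, lp)
  expect_length(tl, 2)
  tracks <- link_tracklets(tl, lp)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$det$frame, c(0:4, 7:11))
  expect_equal(tracks[[1]]$joins, 1L)
})

test_that("distant simultaneous tracklets stay separate", {
  a <- fx_line_track(5, dx = 1, id = 1)
  b <- fx_line_track(5, dx = 1, x0 = 200, y0 = 200, id = 2)
  tracks <- link_tracklets(list(a, b), link_params())
  expect_length(tracks, 2)
})

test_that("linking conserves the detection multiset", {
  set.seed(17)
  det <- data.frame(frame = rep(0:19, each = 3),
                    x = runif(60, 0, 50), y = runif(60, 0, 50),
                    roi_mean = runif(60, 50, 150))
  lp <- link_params(passes = list(list(), list(pair_gate_px = 30)))
  tl <- form_tracklets(det, lp)
  tracks <- multi_pass_link(tl, lp)
  got <- do.call(rbind, lapply(tracks, function(t)
    t$det[, c("frame", "x", "y")]))
  got <- got[order(got$frame, got$x), ]
  want <- det[order(det$frame, det$x), c("frame", "x", "y")]
  expect_equal(got, want, ignore_attr = TRUE)
  # no detection appears in two tracks and frames increase within tracks
  expect_equal(nrow(got), nrow(det))
  for (t in tracks) expect_true(all(diff(t$det$frame) > 0))
})

test_that("a second pass with a larger gate links the fast particle", {
  slow <- list(fx_line_track(4, dx = 1, id = 1, brightness = rep(100, 4)),
               fx_line_track(4, dx = 1, x0 = 5, frames = 5:8, id = 2,
                             brightness = rep(100, 4)))
  fast <- list(fx_line_track(4, dx = 10, y0 = 100, id = 3,
                             brightness = rep(100, 4)),
               fx_line_track(4, dx = 10, x0 = 50, y0 = 100, frames = 5:8,
                             id = 4, brightness = rep(100, 4)))
  lp <- link_params(pair_gate_px = 5,
                    passes = list(list(pair_gate_px = 5),
                                  list(pair_gate_px = 25)))
  pass1 <- link_tracklets(c(slow, fast), modifyList(lp, list()), 1L)
  expect_length(pass1, 3)                      # slow pair joined only
  tracks <- multi_pass_link(c(slow, fast), lp)
  expect_length(tracks, 2)
  joins <- sort(unlist(lapply(tracks, `[[`, "joins")))
  expect_equal(joins, c(1L, 2L))
})

test_that("single-pass multi-pass equals plain linking", {
  set.seed(23)
  det <- data.frame(frame = rep(0:9, each = 2), x = runif(20, 0, 30),
                    y = runif(20, 0, 30), roi_mean = 100)
  lp <- link_params(passes = list(list()))
  tl <- form_tracklets(det, lp)
  expect_equal(multi_pass_link(tl, lp), link_tracklets(tl, lp))
})

test_that("length and net-distance filters follow the stated thresholds", {
  mk <- function(net_px, id) fx_line_track(5, dx = net_px / 4, id = id)
  tracks <- list(mk(5, 1), mk(12, 2), mk(30, 3))   # 500/1200/3000 nm at 100 nm px
  expect_length(filter_tracks(tracks, min_net_len_nm = 700,
                              pixel_size_nm = 100), 2)
  expect_length(filter_tracks(tracks, min_net_len_nm = 1000,
                              pixel_size_nm = 100), 2)
  expect_error(filter_tracks(tracks, min_net_len_nm = 700),
               "pixel_size_nm")
  two_pt <- new_track(9, 0:1, c(0, 1), c(0, 0))
  expect_length(filter_tracks(c(tracks, list(two_pt)), min_points = 3), 3)
})
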